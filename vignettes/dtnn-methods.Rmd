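---
title: "Deep tensor neural networks for molecular energies: model, training and interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep tensor neural networks for molecular energies: model, training and interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtnn)
```

## The model

A deep tensor neural network (DTNN) predicts a molecular energy $E_M$ from
nothing but the nuclear charges $Z_1,\dots,Z_N$ and the interatomic
distances $D_{ij}$. The energy is written as a sum of per-atom
contributions,

$$E_M = \sum_{i=1}^{N} E_i,$$

which makes the prediction invariant under atom reindexing and extensive in
the number of non-interacting fragments by construction. Because only
distances enter, rotations, translations and reflections of the geometry
cannot change the output. These are structural guarantees of the
architecture, not learned behaviours, and the test suite checks them as
exact numerical identities.

Each atom starts from a learnable embedding $c_i^{(0)} = c_{Z_i}$, a vector
of $B$ coefficients per element (default $B = 30$), loosely analogous to an
atomic basis-set expansion. The embedding is then refined by $T$
interaction passes (default $T = 2$): at pass $t$ every atom receives an
additive correction from every other atom within the cutoff,

$$c_i^{(t)} = c_i^{(t-1)} + \sum_{j \ne i} v_{ij},$$

with all updates computed synchronously from the pass-input coefficients.
One pass captures pairwise structure; repeated passes correlate
neighbourhoods of increasing complexity (walks of length $T$ through the
molecular graph), which is how a distance-only model picks up effectively
angular information.

### Distance featurization

A scalar distance is a poor input for a linear layer, so each $D_{ij}$ is
expanded on a uniform grid of Gaussians,

$$\hat d_{ij}[k] = \exp\!\left(-\frac{(D_{ij}-\mu_k)^2}{2\sigma^2}\right),
\qquad \mu_k = \mu_{\min} + k\,\Delta\mu .$$

Defaults are $\Delta\mu = \sigma = 0.2$ Å with $\mu_{\min} = -1$ Å, read as
a length like every other grid quantity; $\mu_{\max}$ should cover the
largest distance in the data (10 Å suits small molecules, 15–20 Å larger
ones). The width is interpreted as a standard deviation; for the
alternative convention $\exp(-\gamma(d-\mu)^2)$ a `gamma` override is
accepted, with $\gamma = 1/(2\sigma^2)$ as the default. Placing the first
center at a negative distance keeps the representation well-conditioned
near zero rather than half-truncating the closest physical distances. No
truncation or sparsification is applied — with at most ~106 centers the
dense vector is cheap.

### The factorized tensor interaction

The interaction $v_{ij}$ must couple the identity of the neighbour (its
current coefficient vector $c_j$) with the geometry (the distance features
$\hat d_{ij}$) multiplicatively. The explicit form is a bilinear tensor
layer, component $k$ being

$$v_{ij}[k] = g\!\left(b_k + (W^c c_j)_k + (W^d \hat d_{ij})_k
  + c_j^{\top} V_k\, \hat d_{ij}\right),$$

with one $B \times G$ slice $V_k$ per output coefficient. That layer has
$O(B^2 G)$ parameters — expensive and prone to overfitting — so the
implementation uses its low-rank factorization through an element-wise
product of projected factors:

$$v_{ij} = g\!\left(W^{fc}\left[(W^{cf} c_j + b^{f1}) \circ
  (W^{df} \hat d_{ij} + b^{f2})\right]\right),$$

with $F$ factors (default 60). Both forms are implemented:
`interaction_factorized()` is the production path, `interaction_full()`
the explicit reference, and `factorized_to_full()` contracts factorized
weights into explicit form,
$V_k[a,g] = \sum_f W^{fc}[k,f]\,W^{cf}[f,a]\,W^{df}[f,g]$, with the linear
and constant terms generated by expanding the factor biases through
$W^{fc}$. With identity activation the two agree to machine precision;
keeping the explicit layer as an independent oracle (checked by a
triple-loop contraction in the tests) guards the factorized code against
silent index errors.

### Energy head and scaling

After the final pass, two fully-connected layers map each refined
coefficient vector to a scaled energy contribution
($H = 15$ hidden units by default), which is then shifted and scaled by
the mean $E_\mu$ and standard deviation $E_\sigma$ of the energy *per
atom* estimated on the training set:

$$o_i = g(W^1 c_i^{(T)} + b^1), \quad
  \hat E_i = W^2 o_i + b^2, \quad
  E_i = E_\sigma \hat E_i + E_\mu .$$

Because $W^2$ and all biases start at zero, an untrained model predicts
exactly $E_\mu$ per atom — the best constant guess — which gives training
a sensible starting point regardless of label scale.

### Choices the architecture description leaves open

* **Nonlinearity.** Fixed to $\tanh$ for the interaction output and the
  head hidden layer, switchable to identity per layer family. A bounded,
  odd, saturating function fits this architecture family and makes
  $g(0)=0$ hold, so a zero distance-factor annihilates the interaction.
* **Weight sharing.** One interaction module applied $T$ times (tied
  weights) is the default, matching the picture of a single refinement
  operator; an untied variant (independent weights per pass) is a flag.
* **Initialization.** Embeddings are drawn i.i.d. normal with s.d.
  $1/\sqrt{B}$; weight matrices are Glorot-uniform; biases and $W^2$ start
  at zero. Construction is bit-reproducible from a single integer seed.
* **Cutoff.** Default none — every pair interacts, appropriate for small
  molecules. A hard cutoff (e.g. 3 Å) restricts direct interactions only;
  with $T$ passes the effective horizon is $T$ times larger. A finite
  cutoff is also what makes strict size extensivity testable: far-separated
  copies decouple exactly.
* **Units.** kcal/mol everywhere internally; Hartree (× 627.509) and eV
  (× 23.0609) are converted at ingest. A single-unit core avoids silent
  unit mismatches between datasets, scalers and reports.

## Training

`dtnn_fit()` minimizes the squared error of molecular energies by
mini-batch stochastic gradient descent with momentum 0.9 at a constant
learning rate, the standard recipe for this architecture. Gradients are
hand-coded backpropagation through the whole computation (embedding table
included), vectorized over a batch via sparse scatter/gather matrices; the
test suite requires agreement with central finite differences to better
than $10^{-5}$ relative (measured by the usual gradient-check ratio
$\lVert g_a - g_n\rVert / (\lVert g_a\rVert + \lVert g_n\rVert)$; observed
agreement is ~$10^{-10}$).

Numerical choices worth knowing:

* **Step normalization.** The per-step gradient of the batch
  sum-of-squares is multiplied by $1/(\text{batch size} \cdot E_\sigma^2)$
  before the update. This is a constant positive rescaling — the optimum
  is unchanged — equivalent to training on per-atom-standardized targets,
  and it lets one learning-rate default (`1e-3`) work across label scales
  from a few kcal/mol to hundreds.
* **Batch size 32, learning rate 1e-3.** Neither is dictated by the
  architecture; both are config keys with these documented defaults.
* **Early stopping = checkpoint-best.** Validation MAE is computed every
  epoch; the returned parameters are those of the epoch with the lowest
  validation MAE. An optional `patience` halts training after that many
  epochs without improvement. The final-epoch parameters are also
  returned (`params_final`) for overfitting diagnostics.
* **Determinism.** All randomness flows from one integer seed; batch
  shuffling is reseeded per epoch from it, so a fixed seed reproduces the
  entire training history bit for bit.
* **Failure handling.** A non-finite loss aborts immediately, naming the
  epoch and batch.

## Synthetic ground truth

Real reference datasets carry quantum-chemical labels that cannot be
recomputed at test time, so the package ships a generator whose labels
have *known, analytic* ground truth: random H/C/O clusters in a box,
rejection-sampled to a minimum interatomic distance and scored by a
pairwise Morse potential

$$E = \sum_{i<j} D_e\!\left[\left(1 - e^{-a(D_{ij}-r_e)}\right)^2 - 1\right],$$

with bond-like parameters per species pair (well depths 35–110 kcal/mol,
equilibrium distances 0.74–1.54 Å). Defaults: 400 clusters of 4–8 atoms in
a 4 Å box, split 80/10/10.

Two generator properties make this a meaningful test bed rather than a
convenience fixture. First, the labels depend only on distances, so they
are exactly invariant under isometries — the generated data probe the
model's invariances with zero label noise. Second, the Morse surface is
exactly pairwise-additive, so a single interaction pass suffices *in
principle* and a second pass must not hurt — a mechanistic expectation a
learned model can be held to. The learning-closure check trains a $T=2$
network on 400 clusters across three seeds and requires validation MAE
below 10% of the label standard deviation; at this problem size
convergence is comfortable within 200 epochs (observed ~6–8% of label
s.d.), far inside the 3000-epoch budget.

The minimum distance default is 1.2 Å, near the shortest bond lengths of
the default pairs. With much smaller values, uniform random placement
oversamples the steep repulsive wall and the dataset degenerates into
hard-clash geometries with heavy-tailed labels — unlike curated sets of
equilibrium structures, whose energy spread comes from composition and
arrangement. At 1.2 Å all sampled clusters are bound (labels roughly −900
to −5 kcal/mol).

What passing these tests does *not* show: Morse clusters have no
electronic structure, no conjugation, no charge transfer, and their
pairwise surface is far simpler than a DFT potential-energy surface.
Closure here validates the optimization and the architecture's capacity
for distance-additive targets, not chemical accuracy on real molecules.
The harmonic pseudo-MD generator (`harmonic_trajectory()`) likewise
emulates only the configurational spread of a hot trajectory — i.i.d.
Gaussian displacements with exact harmonic labels — not real dynamics.

## Interpretation instruments

**Atomic partition.** $E_M = \sum_i E_i$ holds exactly, so any atom subset
has a well-defined energy. `substructure_energy()` sums contributions over
a caller-supplied index set (e.g. a ring), and `rank_by_substructure()`
orders molecules by that score with deterministic lexicographic
tie-breaks. No aromaticity perception is attempted; a convenience helper
finds all-carbon six-cycles in a caller-supplied bond list.

**Local chemical potential.** A probe atom of species $A$ at position $r$
is embedded and refined against the molecule's stored per-pass
coefficients using the probe–atom distances; at pass $t$ it sees the same
pass-input coefficients the molecule's own atoms see. The coupling is
strictly one-way — the molecule's coefficients are computed without the
probe, so its energies are bitwise unchanged by any probe computation (a
property the tests assert with `identical()`, not a tolerance). The
resulting field $\Omega_M^A(r)$ on a regular grid is exported as a
Gaussian cube file (lengths in bohr per the format convention, values in
kcal/mol). For surface visualization the package provides the
inverse-square atom-sum field $\sum_i \lVert r - r_i \rVert^{-2}$
(units Å$^{-2}$), whose level set at 3.8 Å$^{-2}$ is the documented
default for wrapping a molecule at roughly constant effective distance;
this functional form is the package's reading of that convention — the
natural atom-sum with those units — recorded here as an assumption.

**Grid evaluation cost.** The molecule's coefficient history is computed
once per grid, and all grid points are refined as one batch; a
$50^3$ grid on a 20-atom molecule is a few matrix products per pass.

## Degenerate inputs and edge behaviour

* Single-atom molecules are legal: no pairs, no refinement, the head is
  applied to the bare embedding.
* A molecule with every pair beyond the cutoff behaves like isolated
  atoms; a probe beyond the cutoff from every atom returns the isolated
  probe-atom energy exactly.
* `fit_energy_stats()` floors $E_\sigma$ at $10^{-8}$ (population s.d.;
  a single-molecule training set hits the floor).
* Grid centers satisfy $G = \lfloor(\mu_{\max}-\mu_{\min})/\Delta\mu\rfloor + 1$
  with an $10^{-9}$ guard against floating-point fencepost errors.
* Far Gaussian features underflow to exact zero beyond ~40 standard
  deviations; this is harmless since the corresponding weights then
  receive no gradient from those pairs.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale by design: the
factorization identity on 50 random instances with $B, G, F \le 8$;
invariance under 100 random symmetry operations; gradient checks on a
3-atom molecule with $B = F = 4$; learning closure on 400 clusters per
seed for 200 epochs (three seeds). These sizes were chosen so each check
isolates one property with clear margins; none of the checks is a claim
about wall-clock performance at production scale.

## Known limitations

* No forces or Hessians (energies only), no periodic boundary conditions,
  no charge or spin states.
* Accuracy on real quantum-chemical datasets depends on training data
  volume far beyond what the shipped synthetic checks exercise.
* Long-range dispersion is not modelled; with a finite cutoff,
  interactions beyond $T \times \text{cutoff}$ are invisible.
* The atomic energy partition is intrinsically non-unique; it is defined
  by the trained model, and its usefulness is comparative (ranking like
  substructures across molecules), not absolute.
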