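# Seeded generators of labelled molecular datasets with known analytic
# ground truth: random atom clusters scored by pairwise potentials and
# harmonic pseudo-MD trajectories. Because the labels depend only on
# interatomic distances, the generated data probe exactly the invariances
# the network is supposed to respect.

# default Morse parameters: roughly bond-like well depths (kcal/mol),
# equilibrium distances (A) and stiffness (1/A) for H/C/O pairs
default_morse_params <- function() {
  list(
    "1-1" = c(D_e = 104, r_e = 0.74, a = 1.9),
    "1-6" = c(D_e = 99, r_e = 1.09, a = 1.8),
    "1-8" = c(D_e = 110, r_e = 0.96, a = 2.2),
    "6-6" = c(D_e = 83, r_e = 1.54, a = 2.0),
    "6-8" = c(D_e = 85, r_e = 1.43, a = 2.2),
    "8-8" = c(D_e = 35, r_e = 1.48, a = 2.5)
  )
}

#' Specify a synthetic cluster dataset
#'
#' Random clusters of atoms in a box, rejection-sampled to respect a
#' minimum interatomic distance and labelled by an analytic pairwise
#' potential. Defaults emulate small organic-like H/C/O clusters whose
#' label spread is a few tens of kcal/mol.
#'
#' @param species Integer nuclear charges to sample.
#' @param weights Sampling weights, one per species.
#' @param n_atoms Length-2 integer range (min, max) of atoms per cluster.
#' @param box_size Cubic box edge (Angstrom); must exceed `2 * min_dist`.
#' @param min_dist Minimum allowed pair distance (Angstrom, > 0). The
#'   default 1.2 A sits near the shortest bond lengths of the default
#'   species, so sampled clusters are bound structures rather than
#'   hard-clash geometries on the repulsive wall — mirroring datasets of
#'   equilibrium structures, whose energies spread by composition and
#'   arrangement rather than by steric collisions.
#' @param potential `"morse"` or `"lennard_jones"`.
#' @param pair_params Named list keyed `"Z1-Z2"` (Z1 <= Z2). Morse entries
#'   carry `D_e` (kcal/mol), `r_e` (A), `a` (1/A); Lennard-Jones entries
#'   `eps` (kcal/mol) and `sigma` (A).
#' @param n_molecules Number of clusters to generate.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(species = c(1L, 6L, 8L), weights = c(0.5, 0.3, 0.2),
                           n_atoms = c(4L, 8L), box_size = 4, min_dist = 1.2,
                           potential = c("morse", "lennard_jones"),
                           pair_params = default_morse_params(),
                           n_molecules = 400L, seed = 0L) {
  potential <- match.arg(potential)
  stopifnot(length(species) == length(weights), all(weights > 0),
            length(n_atoms) == 2, n_atoms[1] >= 1, n_atoms[2] >= n_atoms[1],
            n_molecules >= 1)
  if (min_dist <= 0) stop("min_dist must be positive", call. = FALSE)
  if (box_size <= 2 * min_dist) {
    stop("box_size must exceed 2 * min_dist", call. = FALSE)
  }
  bad <- vapply(pair_params, function(p) any(p <= 0), logical(1))
  if (any(bad)) stop("pair potential parameters must be positive", call. = FALSE)
  structure(
    list(species = as.integer(species), weights = weights / sum(weights),
         n_atoms = as.integer(n_atoms), box_size = box_size,
         min_dist = min_dist, potential = potential, pair_params = pair_params,
         n_molecules = as.integer(n_molecules), seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

pair_key <- function(z1, z2) paste(min(z1, z2), max(z1, z2), sep = "-")

#' Generate one random atom cluster
#'
#' Atoms are placed sequentially at uniform positions in the box,
#' resampling any position closer than `min_dist` to an already-placed
#' atom; 1e4 consecutive rejections raise a packing-infeasibility error.
#'
#' @param spec A [synthetic_spec()].
#' @param n_atoms Optional atom count (default: sampled from the spec
#'   range).
#' @param seed Optional seed overriding `spec$seed`.
#' @return An unlabelled [molecule()].
#' @export
random_cluster <- function(spec, n_atoms = NULL, seed = spec$seed) {
  with_seed(seed, {
    if (is.null(n_atoms)) {
      n_atoms <- sample(seq(spec$n_atoms[1], spec$n_atoms[2]), 1L)
    }
    Z <- sample(spec$species, n_atoms, replace = TRUE, prob = spec$weights)
    R <- matrix(0, n_atoms, 3)
    for (i in seq_len(n_atoms)) {
      rejections <- 0L
      repeat {
        cand <- stats::runif(3, 0, spec$box_size)
        if (i == 1L ||
            min(sqrt(colSums((t(R[seq_len(i - 1L), , drop = FALSE]) - cand)^2))) >=
              spec$min_dist) {
          R[i, ] <- cand
          break
        }
        rejections <- rejections + 1L
        if (rejections >= 1e4) {
          stop("packing infeasible: 1e4 consecutive rejections placing atom ", i,
               call. = FALSE)
        }
      }
    }
    molecule(Z, R)
  })
}

#' Analytic pairwise potential energy of a cluster
#'
#' Morse form `sum_{i<j} D_e * ((1 - exp(-a (D_ij - r_e)))^2 - 1)` or
#' Lennard-Jones `sum_{i<j} 4 eps ((sigma/r)^12 - (sigma/r)^6)`; exactly
#' pairwise-additive and dependent on distances only.
#'
#' @param mol A [molecule()].
#' @param spec A [synthetic_spec()] holding the pair parameters.
#' @return Scalar energy (kcal/mol).
#' @export
pair_potential_energy <- function(mol, spec) {
  N <- length(mol$Z)
  if (N < 2) return(0)
  D <- distance_matrix(mol)
  total <- 0
  for (i in seq_len(N - 1)) {
    for (j in (i + 1):N) {
      p <- spec$pair_params[[pair_key(mol$Z[i], mol$Z[j])]]
      if (is.null(p)) {
        stop("no pair parameters for species pair ",
             pair_key(mol$Z[i], mol$Z[j]), call. = FALSE)
      }
      r <- D[i, j]
      total <- total + switch(spec$potential,
        morse = p[["D_e"]] * ((1 - exp(-p[["a"]] * (r - p[["r_e"]])))^2 - 1),
        lennard_jones = 4 * p[["eps"]] *
          ((p[["sigma"]] / r)^12 - (p[["sigma"]] / r)^6)
      )
    }
  }
  total
}

#' Harmonic pseudo-MD trajectory around a reference geometry
#'
#' Frames are the reference plus i.i.d. Gaussian displacements (standard
#' deviation `temperature_scale` per Cartesian coordinate), labelled by
#' the harmonic restoring energy `0.5 * k_spring * ||R - R_ref||^2`,
#' optionally plus the spec's pair potential. This emulates the
#' configurational spread of a hot MD trajectory without integrating any
#' dynamics.
#'
#' @param ref Reference [molecule()].
#' @param k_spring Spring constant (kcal/mol/A^2).
#' @param temperature_scale Displacement s.d. (Angstrom; 0 gives identical
#'   frames with zero labels).
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param spec Optional [synthetic_spec()]; when given, the pair potential
#'   is added to each label.
#' @return A labelled [mol_dataset()].
#' @export
harmonic_trajectory <- function(ref, k_spring = 100, temperature_scale = 0.05,
                                n_frames = 100L, seed = 0L, spec = NULL) {
  stopifnot(k_spring >= 0, temperature_scale >= 0, n_frames >= 1)
  with_seed(seed, {
    frames <- lapply(seq_len(n_frames), function(f) {
      disp <- matrix(stats::rnorm(length(ref$R), sd = temperature_scale),
                     nrow = nrow(ref$R))
      if (temperature_scale == 0) disp[] <- 0
      R <- ref$R + disp
      e <- 0.5 * k_spring * sum(disp^2)
      m <- molecule(ref$Z, R, id = sprintf("frame_%04d", f))
      if (!is.null(spec)) e <- e + pair_potential_energy(m, spec)
      m$energy <- e
      m
    })
    mol_dataset(frames)
  })
}

#' Generate a labelled, pre-split synthetic dataset
#'
#' `n_molecules` random clusters labelled by the spec's pair potential and
#' split 80/10/10 (train/val/test) with the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A labelled [mol_dataset()] with split labels.
#' @export
make_dataset <- function(spec) {
  molecules <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_molecules), function(i) {
      mol <- random_cluster(spec, seed = NULL)
      mol$id <- sprintf("cluster_%05d", i)
      mol$energy <- pair_potential_energy(mol, spec)
      mol
    })
  })
  split_dataset(mol_dataset(molecules), c(0.8, 0.1, 0.1), seed = spec$seed)
}
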