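# Deep tensor neural network: per-element embeddings refined by factorized
# tensor interaction passes over Gaussian-expanded distances, with a
# two-layer per-atom energy head. The molecular energy is the sum of atomic
# contributions, so permutation invariance and size extensivity hold by
# construction; rotation/translation invariance holds because only
# interatomic distances enter.

act_fun <- function(x, type) {
  switch(type, tanh = tanh(x), identity = x,
         stop("unknown activation: ", type, call. = FALSE))
}

# derivative expressed through the activation *output*
act_grad_from_out <- function(y, type) {
  switch(type, tanh = 1 - y^2, identity = y * 0 + 1,
         stop("unknown activation: ", type, call. = FALSE))
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

#' Initialize DTNN parameters
#'
#' Embedding coefficients are drawn from a zero-mean normal with standard
#' deviation `1/sqrt(B)`; weight matrices use Glorot-uniform
#' initialization; all biases and the final head layer start at zero, so
#' an untrained model predicts the training-set mean energy per atom.
#'
#' @param species Integer nuclear charges the model can embed.
#' @param grid A [gaussian_grid()] defining the distance features.
#' @param B Embedding width (coefficients per atom).
#' @param n_factors Number of factors F in the low-rank tensor
#'   factorization.
#' @param H Hidden units in the energy head.
#' @param n_passes Number of interaction passes T (1-3 typical).
#' @param cutoff Optional hard interaction cutoff in Angstrom (`NULL` =
#'   all pairs interact).
#' @param tied Share interaction weights across passes (default) or give
#'   each pass its own.
#' @param activation Nonlinearity for the interaction output and the head
#'   hidden layer: `"tanh"` (default) or `"identity"`.
#' @param seed Integer seed; construction is bit-reproducible for a fixed
#'   seed.
#' @return An object of class `"dtnn_params"`.
#' @export
dtnn_init <- function(species, grid, B = 30L, n_factors = 60L, H = 15L,
                      n_passes = 2L, cutoff = NULL, tied = TRUE,
                      activation = "tanh", seed = 0L) {
  stopifnot(inherits(grid, "gaussian_grid"), B >= 1, n_factors >= 1, H >= 1,
            n_passes >= 1)
  if (!is.null(cutoff) && cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  species <- sort(unique(as.integer(species)))
  if (any(species < 1)) stop("nuclear charges must be >= 1", call. = FALSE)
  G <- grid$G
  with_seed(seed, {
    emb <- matrix(stats::rnorm(B * length(species), sd = 1 / sqrt(B)), B,
                  dimnames = list(NULL, as.character(species)))
    n_blocks <- if (tied) 1L else as.integer(n_passes)
    inter <- lapply(seq_len(n_blocks), function(t) {
      list(
        W_cf = glorot(n_factors, B), b_f1 = numeric(n_factors),
        W_df = glorot(n_factors, G), b_f2 = numeric(n_factors),
        W_fc = glorot(B, n_factors)
      )
    })
    head <- list(W1 = glorot(H, B), b1 = numeric(H),
                 W2 = numeric(H), b2 = 0)
    structure(
      list(species = species, emb = emb, inter = inter, head = head,
           B = as.integer(B), n_factors = as.integer(n_factors),
           H = as.integer(H), n_passes = as.integer(n_passes),
           cutoff = cutoff, tied = tied, activation = activation, grid = grid),
      class = "dtnn_params"
    )
  })
}

#' @export
print.dtnn_params <- function(x, ...) {
  cat(sprintf(
    "<dtnn_params: B=%d, F=%d, H=%d, T=%d, G=%d, %s weights, cutoff=%s, species [%s]>\n",
    x$B, x$n_factors, x$H, x$n_passes, x$grid$G,
    if (x$tied) "tied" else "untied",
    if (is.null(x$cutoff)) "none" else paste0(x$cutoff, " A"),
    paste(z_to_symbol(x$species), collapse = ",")
  ))
  invisible(x)
}

# interaction weight block for a given pass (1-based)
inter_block <- function(params, pass) {
  params$inter[[if (params$tied) 1L else pass]]
}

#' Per-atom energy scaler
#'
#' Atomic head outputs are scaled by `E_sigma` and shifted by `E_mu`, the
#' standard deviation and mean of the energy per atom estimated on the
#' training set; with a zero-initialized final head layer the untrained
#' prediction is `E_mu` per atom.
#'
#' @param E_mu Mean energy per atom (kcal/mol).
#' @param E_sigma Standard deviation of energy per atom (kcal/mol, > 0).
#' @return An object of class `"energy_scaler"`.
#' @export
energy_scaler <- function(E_mu = 0, E_sigma = 1) {
  stopifnot(is.finite(E_mu), is.finite(E_sigma), E_sigma > 0)
  structure(list(E_mu = E_mu, E_sigma = E_sigma), class = "energy_scaler")
}

#' Assign initial coefficient vectors from nuclear charges
#'
#' @param Z Integer nuclear charges.
#' @param params A [dtnn_init()] parameter set.
#' @return An atomic state: list with `coeffs` (N x B matrix, row i the
#'   embedding of atom i) and pass counter `t = 0`.
#' @export
embed <- function(Z, params) {
  Z <- as.integer(Z)
  missing <- setdiff(Z, params$species)
  if (length(missing)) {
    stop("nuclear charge(s) not in the embedding table: ",
         paste(sort(missing), collapse = ", "), call. = FALSE)
  }
  coeffs <- t(params$emb[, as.character(Z), drop = FALSE])
  rownames(coeffs) <- NULL
  structure(list(coeffs = coeffs, t = 0L), class = "atomic_state")
}

#' Factorized pairwise interaction term
#'
#' Low-rank tensor interaction: the atom representation and the distance
#' features are projected to a common factor space, combined by an
#' element-wise product and projected back,
#' `v_ij = g(W_fc ((W_cf c_j + b_f1) * (W_df dhat_ij + b_f2)))`.
#'
#' @param c_j Coefficient vector of the influencing atom (length B).
#' @param dhat Distance feature vector (length G).
#' @param params A [dtnn_init()] parameter set.
#' @param pass Pass index (matters only for untied weights).
#' @return Interaction vector of length B.
#' @export
interaction_factorized <- function(c_j, dhat, params, pass = 1L) {
  w <- inter_block(params, pass)
  if (length(c_j) != params$B) stop("c_j must have length B = ", params$B, call. = FALSE)
  if (length(dhat) != params$grid$G) {
    stop("dhat must have length G = ", params$grid$G, call. = FALSE)
  }
  f <- (w$W_cf %*% c_j + w$b_f1) * (w$W_df %*% dhat + w$b_f2)
  as.vector(act_fun(w$W_fc %*% f, params$activation))
}

#' Explicit tensor-layer parameters
#'
#' The unfactorized bilinear interaction layer, kept as an independent
#' reference for the factorized form: output k is
#' `g(b[k] + (W_c c)_k + (W_d dhat)_k + c' V[k,,] dhat)`.
#'
#' @param V B x B x G array; slice `V[k, , ]` combines the inputs
#'   multiplicatively for output coefficient k.
#' @param W_c B x B linear weights on the atom representation.
#' @param W_d B x G linear weights on the distance features.
#' @param b Length-B bias.
#' @param activation Nonlinearity.
#' @return An object of class `"oracle_tensor_params"`.
#' @export
oracle_tensor_params <- function(V, W_c, W_d, b, activation = "tanh") {
  stopifnot(length(dim(V)) == 3, dim(V)[1] == dim(V)[2],
            all(dim(W_c) == dim(V)[1:2]),
            nrow(W_d) == dim(V)[1], ncol(W_d) == dim(V)[3],
            length(b) == dim(V)[1])
  structure(list(V = V, W_c = W_c, W_d = W_d, b = b, activation = activation),
            class = "oracle_tensor_params")
}

#' Explicit (full-rank) tensor-layer interaction
#'
#' @param c_j Coefficient vector (length B).
#' @param dhat Distance feature vector (length G).
#' @param oracle An [oracle_tensor_params()].
#' @return Interaction vector of length B.
#' @export
interaction_full <- function(c_j, dhat, oracle) {
  B <- length(oracle$b)
  stopifnot(length(c_j) == B, length(dhat) == dim(oracle$V)[3])
  bilinear <- vapply(seq_len(B), function(k) {
    as.numeric(c_j %*% oracle$V[k, , ] %*% dhat)
  }, numeric(1))
  pre <- oracle$b + as.vector(oracle$W_c %*% c_j) +
    as.vector(oracle$W_d %*% dhat) + bilinear
  act_fun(pre, oracle$activation)
}

#' Collapse factorized interaction weights into explicit tensor form
#'
#' Contracts `V[k, a, g] = sum_f W_fc[k, f] W_cf[f, a] W_df[f, g]`, with
#' the linear and constant terms generated by the factor biases expanded
#' through `W_fc`. With identity activation the explicit layer built this
#' way reproduces the factorized layer exactly.
#'
#' @param params A [dtnn_init()] parameter set.
#' @param pass Pass index.
#' @return An [oracle_tensor_params()].
#' @export
factorized_to_full <- function(params, pass = 1L) {
  w <- inter_block(params, pass)
  B <- params$B; G <- params$grid$G; F <- params$n_factors
  V <- array(0, dim = c(B, B, G))
  for (k in seq_len(B)) {
    # sum_f W_fc[k,f] * outer(W_cf[f,], W_df[f,])
    V[k, , ] <- t(w$W_cf) %*% (w$W_fc[k, ] * w$W_df)
  }
  oracle_tensor_params(
    V = V,
    W_c = w$W_fc %*% (w$b_f2 * w$W_cf),
    W_d = w$W_fc %*% (w$b_f1 * w$W_df),
    b = as.vector(w$W_fc %*% (w$b_f1 * w$b_f2)),
    activation = params$activation
  )
}

#' One interaction refinement pass
#'
#' Every atom's coefficient vector is incremented by the sum of factorized
#' interaction terms from all other atoms within the cutoff:
#' `c_i <- c_i + sum_{j != i, D_ij <= cutoff} v_ij`. All atoms update
#' synchronously from the pass-input coefficients.
#'
#' @param state An atomic state from [embed()] or a previous pass.
#' @param D Distance matrix of the molecule.
#' @param feats N x N x G feature array from [expand_all()].
#' @param params A [dtnn_init()] parameter set.
#' @return The refined atomic state with `t` incremented.
#' @export
refine_pass <- function(state, D, feats, params) {
  N <- nrow(state$coeffs)
  stopifnot(nrow(D) == N, dim(feats)[1] == N, dim(feats)[3] == params$grid$G)
  pass <- state$t + 1L
  pairs <- which(upper.tri(D) | lower.tri(D), arr.ind = TRUE)
  if (!is.null(params$cutoff)) {
    pairs <- pairs[D[pairs] <= params$cutoff, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) {
    state$t <- pass
    return(state)
  }
  w <- inter_block(params, pass)
  C <- t(state$coeffs)                                  # B x N
  Dhat <- matrix(feats[cbind(rep(pairs[, 1], each = params$grid$G),
                             rep(pairs[, 2], each = params$grid$G),
                             rep.int(seq_len(params$grid$G), nrow(pairs)))],
                 nrow = params$grid$G)                  # G x P
  f <- (w$W_cf %*% C[, pairs[, 2], drop = FALSE] + w$b_f1) *
    (w$W_df %*% Dhat + w$b_f2)
  V <- act_fun(w$W_fc %*% f, params$activation)         # B x P
  S <- Matrix::sparseMatrix(i = seq_len(nrow(pairs)), j = pairs[, 1],
                            x = 1, dims = c(nrow(pairs), N))
  state$coeffs <- state$coeffs + t(as.matrix(V %*% S))
  state$t <- pass
  state
}

#' Per-atom energies from the final atomic state
#'
#' Two fully-connected layers map each refined coefficient vector to a
#' scaled energy contribution, which the scaler shifts back to physical
#' units: `o_i = g(W1 c_i + b1)`, `Ehat_i = W2 o_i + b2`,
#' `E_i = E_sigma * Ehat_i + E_mu`.
#'
#' @param state Atomic state after the final pass.
#' @param params A [dtnn_init()] parameter set.
#' @param scaler An [energy_scaler()].
#' @return Numeric vector of per-atom energies (kcal/mol).
#' @export
atomic_energies <- function(state, params, scaler) {
  O <- act_fun(params$head$W1 %*% t(state$coeffs) + params$head$b1,
               params$activation)                       # H x N
  ehat <- as.vector(params$head$W2 %*% O) + params$head$b2
  scaler$E_sigma * ehat + scaler$E_mu
}

#' Molecular energy prediction
#'
#' Runs the full forward computation: embedding, T interaction passes,
#' per-atom energy head; the molecular energy is the sum of atomic
#' contributions.
#'
#' @param mol A [molecule()].
#' @param params A [dtnn_init()] parameter set.
#' @param scaler An [energy_scaler()].
#' @return List with `energy` (scalar E_M, kcal/mol) and `atomic`
#'   (per-atom contributions E_i summing exactly to E_M).
#' @export
molecular_energy <- function(mol, params, scaler) {
  D <- distance_matrix(mol)
  feats <- expand_all(D, params$grid)
  state <- embed(mol$Z, params)
  for (t in seq_len(params$n_passes)) {
    state <- refine_pass(state, D, feats, params)
  }
  E <- atomic_energies(state, params, scaler)
  list(energy = sum(E), atomic = E)
}

# Internal: coefficient matrices of the molecule for passes t = 0..T,
# computed once without any probe; element [[t+1]] is the pass-t state.
coeff_history <- function(mol, params) {
  D <- distance_matrix(mol)
  feats <- expand_all(D, params$grid)
  state <- embed(mol$Z, params)
  hist <- vector("list", params$n_passes + 1L)
  hist[[1L]] <- state$coeffs
  for (t in seq_len(params$n_passes)) {
    state <- refine_pass(state, D, feats, params)
    hist[[t + 1L]] <- state$coeffs
  }
  hist
}

#' Local chemical potential at a point: probe-atom energy
#'
#' A probe atom of species `probe_Z` is placed at position `r` and refined
#' T times against the molecule's coefficient vectors, using the probe-atom
#' distances; the coupling is one-way — the molecule's own coefficients
#' (and hence its energies) are computed without the probe and are bitwise
#' unaffected by it. The returned value is the energy head applied to the
#' final probe coefficient vector.
#'
#' @param mol A [molecule()].
#' @param probe_Z Nuclear charge of the probe species.
#' @param r Length-3 position (Angstrom).
#' @param params A [dtnn_init()] parameter set.
#' @param scaler An [energy_scaler()].
#' @param history Optional precomputed coefficient history (internal reuse
#'   when evaluating many probe positions).
#' @return Scalar probe energy Omega (kcal/mol).
#' @export
probe_energy <- function(mol, probe_Z, r, params, scaler, history = NULL) {
  stopifnot(length(r) == 3, all(is.finite(r)))
  if (is.null(history)) history <- coeff_history(mol, params)
  probe_Z <- as.integer(probe_Z)
  if (!probe_Z %in% params$species) {
    stop("probe nuclear charge not in the embedding table: ", probe_Z, call. = FALSE)
  }
  d <- sqrt(colSums((t(mol$R) - r)^2))
  keep <- if (is.null(params$cutoff)) seq_along(d) else which(d <= params$cutoff)
  p <- params$emb[, as.character(probe_Z)]
  Dhat <- expand_cols(d[keep], params$grid)
  for (t in seq_len(params$n_passes)) {
    if (length(keep)) {
      w <- inter_block(params, t)
      Cmol <- t(history[[t]][keep, , drop = FALSE])     # B x n
      f <- (w$W_cf %*% Cmol + w$b_f1) * (w$W_df %*% Dhat + w$b_f2)
      p <- p + rowSums(act_fun(w$W_fc %*% f, params$activation))
    }
  }
  o <- act_fun(params$head$W1 %*% p + params$head$b1, params$activation)
  scaler$E_sigma * (sum(params$head$W2 * o) + params$head$b2) + scaler$E_mu
}
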