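# Shared fixtures: tiny grids, small randomized models, reference
# geometries and a pocket Morse spec. Everything is generated in code.

tiny_grid <- function() gaussian_grid(-1, 4, 0.5, 0.5)

# a small model with every weight (including the normally zero-initialized
# head output layer and biases) randomized, so forward outputs are nonzero
tiny_params <- function(species = c(1L, 6L, 8L), grid = tiny_grid(),
                        B = 6L, F = 8L, H = 4L, T = 2L, cutoff = NULL,
                        activation = "tanh", seed = 11L) {
  p <- dtnn_init(species, grid, B = B, n_factors = F, H = H, n_passes = T,
                 cutoff = cutoff, activation = activation, seed = seed)
  set.seed(seed + 1L)
  for (i in seq_along(p$inter)) {
    p$inter[[i]]$b_f1 <- stats::rnorm(F, sd = 0.2)
    p$inter[[i]]$b_f2 <- stats::rnorm(F, sd = 0.2)
  }
  p$head$b1 <- stats::rnorm(H, sd = 0.2)
  p$head$W2 <- stats::rnorm(H, sd = 0.5)
  p$head$b2 <- stats::rnorm(1, sd = 0.2)
  p
}

water <- function(energy = NULL) {
  molecule(c(8L, 1L, 1L),
           rbind(c(0, 0, 0), c(0.9572, 0, 0), c(-0.2399, 0.9266, 0)),
           energy = energy, id = "water")
}

random_molecule <- function(n = 5L, species = c(1L, 6L, 8L), scale = 2,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  molecule(sample(species, n, replace = TRUE),
           matrix(stats::rnorm(3 * n, sd = scale), n, 3))
}

random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

small_morse_spec <- function(n_molecules = 20L, n_atoms = c(3L, 3L), seed = 0L) {
  synthetic_spec(n_atoms = n_atoms, n_molecules = n_molecules, seed = seed)
}

# flatten / restore the trainable parameter structure (finite-difference
# gradient checks)
flatten_params <- function(x) {
  if (is.list(x)) unlist(lapply(x, flatten_params), use.names = FALSE)
  else as.numeric(x)
}

unflatten_params <- function(theta, template) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    v <- theta[(i + 1L):(i + n)]
    i <<- i + n
    if (is.matrix(x)) {
      m <- matrix(v, nrow(x), ncol(x)); dimnames(m) <- dimnames(x); m
    } else v
  }
  rec(template)
}
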