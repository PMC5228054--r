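# Gaussian expansion of interatomic distances on a uniform grid of centers.

#' Define a uniform grid of Gaussians for distance expansion
#'
#' A scalar distance d is encoded as the vector of responses
#' exp(-(d - mu_k)^2 / (2 sigma^2)) on centers mu_k = mu_min + k * delta_mu.
#' Spreading distances across many dimensions lets the interaction layer
#' treat different distance regimes with different weights. Defaults follow
#' the common setting delta_mu = sigma = 0.2 A with the first center at
#' -1 A; `mu_max` should cover the largest distance in the data (10 A
#' suits small organic molecules; 15-20 A larger ones).
#'
#' @param mu_min Center of the first Gaussian (Angstrom).
#' @param mu_max Upper bound for centers (Angstrom); the last center is the
#'   largest `mu_min + k * delta_mu <= mu_max`.
#' @param delta_mu Gap between adjacent centers (Angstrom, > 0).
#' @param sigma Gaussian width, read as a standard deviation (Angstrom, > 0).
#' @param gamma Optional exponential coefficient overriding the
#'   `1/(2 sigma^2)` convention, for the alternative parameterization
#'   exp(-gamma (d - mu)^2).
#' @return An object of class `"gaussian_grid"` with elements `centers`
#'   (ordered, spacing exactly `delta_mu`) and `G` (their number).
#' @examples
#' g <- gaussian_grid(-1, 10, 0.2, 0.2)
#' g$G
#' @export
gaussian_grid <- function(mu_min = -1, mu_max = 10, delta_mu = 0.2, sigma = 0.2,
                          gamma = NULL) {
  stopifnot(delta_mu > 0, sigma > 0, mu_max > mu_min)
  G <- as.integer(floor((mu_max - mu_min) / delta_mu + 1e-9)) + 1L
  centers <- mu_min + (seq_len(G) - 1L) * delta_mu
  if (is.null(gamma)) gamma <- 1 / (2 * sigma^2)
  structure(
    list(mu_min = mu_min, mu_max = mu_max, delta_mu = delta_mu, sigma = sigma,
         gamma = gamma, centers = centers, G = G),
    class = "gaussian_grid"
  )
}

#' @export
print.gaussian_grid <- function(x, ...) {
  cat(sprintf("<gaussian_grid: %d centers in [%g, %g] A, delta_mu = %g, sigma = %g>\n",
              x$G, x$centers[1], x$centers[x$G], x$delta_mu, x$sigma))
  invisible(x)
}

#' Expand a distance on a Gaussian grid
#'
#' @param d Non-negative scalar distance (Angstrom).
#' @param grid A [gaussian_grid()].
#' @return Numeric feature vector of length `grid$G`, components in (0, 1].
#' @examples
#' g <- gaussian_grid(-1, 10, 0.2, 0.2)
#' gaussian_expand(1.4, g)[13]  # d on a center -> exactly 1
#' @export
gaussian_expand <- function(d, grid) {
  stopifnot(inherits(grid, "gaussian_grid"), length(d) == 1L, is.finite(d))
  if (d < 0) stop("distance must be non-negative", call. = FALSE)
  exp(-grid$gamma * (d - grid$centers)^2)
}

#' Expand a full distance matrix
#'
#' @param D Symmetric N x N distance matrix.
#' @param grid A [gaussian_grid()].
#' @return N x N x G array; slice `[i, j, ]` equals
#'   `gaussian_expand(D[i, j], grid)`. The diagonal is present but never
#'   consumed (interaction sums skip j = i).
#' @export
expand_all <- function(D, grid) {
  stopifnot(inherits(grid, "gaussian_grid"), is.matrix(D), nrow(D) == ncol(D))
  N <- nrow(D)
  d <- as.vector(D)
  feat <- exp(-grid$gamma * (rep(d, times = grid$G) -
                               rep(grid$centers, each = N * N))^2)
  array(feat, dim = c(N, N, grid$G))
}

# Internal: expand a vector of distances into a G x P column matrix
# (one column per distance), the layout used by the batched network code.
expand_cols <- function(d, grid) {
  P <- length(d)
  if (P == 0L) return(matrix(0, grid$G, 0))
  matrix(
    exp(-grid$gamma * (rep(d, each = grid$G) - rep(grid$centers, times = P))^2),
    nrow = grid$G
  )
}
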