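test_that("embed maps identical charges to identical rows and rejects unknowns", {
  p <- tiny_params()
  st <- embed(c(1L, 1L), p)
  expect_identical(st$coeffs[1, ], st$coeffs[2, ])
  expect_identical(st$t, 0L)
  st2 <- embed(c(6L, 1L), p)
  expect_false(identical(st2$coeffs[1, ], st2$coeffs[2, ]))
  expect_error(embed(c(0L, 1L), p), "0")
  expect_error(embed(7L, p), "7")
})

test_that("factorized interaction annihilates on zero distance features", {
  p <- dtnn_init(c(1, 6), tiny_grid(), B = 4, n_factors = 5, H = 3,
                 n_passes = 1, seed = 2)
  # zero factor biases (the initialization default) and dhat = 0 force the
  # element-wise product, hence tanh(0) = 0
  v <- interaction_factorized(rnorm(4), numeric(tiny_grid()$G), p)
  expect_identical(v, numeric(4))
  # determinism
  c_j <- rnorm(4); dhat <- runif(tiny_grid()$G)
  expect_identical(interaction_factorized(c_j, dhat, p),
                   interaction_factorized(c_j, dhat, p))
  expect_error(interaction_factorized(rnorm(3), dhat, p), "length B")
  expect_error(interaction_factorized(c_j, dhat[-1], p), "length G")
})

test_that("interaction_full reproduces scalar bilinear arithmetic", {
  # B = G = 1, V = 2, c = 3, d = 4, identity activation -> 2*3*4 = 24
  o <- oracle_tensor_params(array(2, c(1, 1, 1)), matrix(0, 1, 1),
                            matrix(0, 1, 1), 0, activation = "identity")
  expect_equal(interaction_full(3, 4, o), 24)
  # all-zero parameters -> g(0)
  o0 <- oracle_tensor_params(array(0, c(2, 2, 3)), matrix(0, 2, 2),
                             matrix(0, 2, 3), c(0, 0), activation = "tanh")
  expect_identical(interaction_full(rnorm(2), rnorm(3), o0), c(0, 0))
})

test_that("interaction_full matches a triple-loop contraction", {
  set.seed(9)
  for (trial in 1:5) {
    B <- sample(2:6, 1); G <- sample(2:6, 1)
    V <- array(rnorm(B * B * G), c(B, B, G))
    W_c <- matrix(rnorm(B * B), B); W_d <- matrix(rnorm(B * G), B)
    b <- rnorm(B)
    o <- oracle_tensor_params(V, W_c, W_d, b, activation = "identity")
    c_j <- rnorm(B); dhat <- rnorm(G)
    loop <- vapply(seq_len(B), function(k) {
      s <- b[k]
      for (a in seq_len(B)) s <- s + W_c[k, a] * c_j[a]
      for (g in seq_len(G)) s <- s + W_d[k, g] * dhat[g]
      for (a in seq_len(B)) for (g in seq_len(G)) {
        s <- s + c_j[a] * V[k, a, g] * dhat[g]
      }
      s
    }, numeric(1))
    expect_equal(interaction_full(c_j, dhat, o), loop, tolerance = 1e-12)
  }
})

test_that("factorized layer equals the collapsed explicit tensor layer", {
  # identity activation: the low-rank factorization contracts exactly to
  # the full bilinear form
  set.seed(21)
  for (trial in 1:10) {
    B <- sample(2:8, 1); G <- sample(2:8, 1); F <- sample(2:8, 1)
    p <- dtnn_init(c(1, 6), gaussian_grid(0, 0.1 * (G - 1) + 1e-9, 0.1, 0.2),
                   B = B, n_factors = F, H = 2, n_passes = 1,
                   activation = "identity", seed = trial)
    p$inter[[1]]$b_f1 <- rnorm(F)
    p$inter[[1]]$b_f2 <- rnorm(F)
    oracle <- factorized_to_full(p)
    c_j <- rnorm(B); dhat <- runif(p$grid$G)
    expect_equal(interaction_full(c_j, dhat, oracle),
                 interaction_factorized(c_j, dhat, p), tolerance = 1e-10)
  }
})

test_that("refine_pass handles degenerate and symmetric cases", {
  p <- tiny_params()
  # single atom: no interaction partners, state unchanged
  m1 <- molecule(6L, matrix(0, 1, 3))
  st <- embed(m1$Z, p)
  D <- distance_matrix(m1); feats <- expand_all(D, p$grid)
  st1 <- refine_pass(st, D, feats, p)
  expect_identical(st1$coeffs, st$coeffs)
  expect_identical(st1$t, 1L)
  # homonuclear diatomic: refined vectors identical by exchange symmetry
  m2 <- molecule(c(1L, 1L), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  D2 <- distance_matrix(m2); f2 <- expand_all(D2, p$grid)
  st2 <- refine_pass(embed(m2$Z, p), D2, f2, p)
  expect_identical(st2$coeffs[1, ], st2$coeffs[2, ])
  expect_false(identical(st2$coeffs, embed(m2$Z, p)$coeffs))
  # cutoff excludes all pairs: state unchanged
  pc <- tiny_params(cutoff = 1)
  m3 <- molecule(c(1L, 6L), rbind(c(0, 0, 0), c(0, 0, 2.5)))
  D3 <- distance_matrix(m3); f3 <- expand_all(D3, pc$grid)
  st3 <- refine_pass(embed(m3$Z, pc), D3, f3, pc)
  expect_identical(st3$coeffs, embed(m3$Z, pc)$coeffs)
})

test_that("refine_pass agrees with the pointwise interaction op", {
  p <- tiny_params()
  m <- random_molecule(4, seed = 31)
  D <- distance_matrix(m); feats <- expand_all(D, p$grid)
  st0 <- embed(m$Z, p)
  st1 <- refine_pass(st0, D, feats, p)
  for (i in 1:4) {
    expected <- st0$coeffs[i, ]
    for (j in setdiff(1:4, i)) {
      expected <- expected +
        interaction_factorized(st0$coeffs[j, ], feats[i, j, ], p)
    }
    expect_equal(st1$coeffs[i, ], expected, tolerance = 1e-12)
  }
})

test_that("atomic energies apply the head and scaler as an affine map", {
  p <- tiny_params()
  m <- random_molecule(3, seed = 5)
  st <- embed(m$Z, p)
  # zeroed output layer forces the mean prediction
  p0 <- p; p0$head$W2 <- numeric(p$H); p0$head$b2 <- 0
  e <- atomic_energies(st, p0, energy_scaler(-7.5, 3))
  expect_equal(e, rep(-7.5, 3))
  # identity scaler passes the raw head output through
  raw <- atomic_energies(st, p, energy_scaler(0, 1))
  scaled <- atomic_energies(st, p, energy_scaler(0, 2))
  expect_equal(scaled, 2 * raw, tolerance = 1e-12)
  shifted <- atomic_energies(st, p, energy_scaler(1.5, 1))
  expect_equal(shifted, raw + 1.5, tolerance = 1e-12)
})

test_that("molecular energy is invariant under permutations and isometries", {
  p <- tiny_params()
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(6, seed = 17)
  ref <- molecular_energy(m, p, sc)
  expect_equal(sum(ref$atomic), ref$energy)
  for (s in 1:25) {
    perm <- sample(6)
    e_p <- molecular_energy(molecule(m$Z[perm], m$R[perm, ]), p, sc)
    expect_equal(e_p$energy, ref$energy, tolerance = 1e-10)
    expect_equal(e_p$atomic, ref$atomic[perm], tolerance = 1e-10)
    Q <- random_rotation(seed = 300 + s)
    shift <- matrix(rnorm(3, sd = 5), 6, 3, byrow = TRUE)
    e_r <- molecular_energy(molecule(m$Z, m$R %*% Q + shift), p, sc)
    expect_equal(e_r$energy, ref$energy, tolerance = 1e-10)
  }
})

test_that("energy is size-extensive for far-separated copies under a cutoff", {
  p <- tiny_params(cutoff = 3)
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(4, seed = 23)
  e1 <- molecular_energy(m, p, sc)$energy
  for (K in 2:3) {
    Z <- rep(m$Z, K)
    R <- do.call(rbind, lapply(seq_len(K) - 1L, function(k) m$R + k * 40))
    eK <- molecular_energy(molecule(Z, R), p, sc)$energy
    expect_equal(eK, K * e1, tolerance = 1e-9)
  }
})

test_that("probe coupling is one-way and respects symmetry and cutoff", {
  p <- tiny_params(cutoff = 3)
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(5, seed = 29)
  before <- molecular_energy(m, p, sc)
  omega <- probe_energy(m, 1L, c(0.3, -0.2, 0.5), p, sc)
  after <- molecular_energy(m, p, sc)
  expect_identical(before$atomic, after$atomic)  # bitwise
  expect_true(is.finite(omega))
  # beyond the cutoff the probe sees nothing: isolated-atom head energy
  far <- probe_energy(m, 1L, c(1000, 0, 0), p, sc)
  iso <- atomic_energies(embed(1L, p), p, sc)
  expect_equal(far, iso, tolerance = 1e-12)
  # mirror-equivalent positions across a homonuclear diatomic
  d2 <- molecule(c(8L, 8L), rbind(c(0, 0, -0.6), c(0, 0, 0.6)))
  o1 <- probe_energy(d2, 1L, c(0.8, 0.3, 0.9), p, sc)
  o2 <- probe_energy(d2, 1L, c(0.8, 0.3, -0.9), p, sc)
  expect_equal(o1, o2, tolerance = 1e-10)
  expect_error(probe_energy(m, 7L, c(0, 0, 0), p, sc), "7")
})

test_that("untied interaction weights differ per pass and change the output", {
  g <- tiny_grid()
  p_tied <- dtnn_init(c(1, 6), g, B = 4, n_factors = 5, H = 3, n_passes = 2,
                      tied = TRUE, seed = 3)
  p_untied <- dtnn_init(c(1, 6), g, B = 4, n_factors = 5, H = 3, n_passes = 2,
                        tied = FALSE, seed = 3)
  expect_length(p_tied$inter, 1L)
  expect_length(p_untied$inter, 2L)
  expect_false(identical(p_untied$inter[[1]]$W_cf, p_untied$inter[[2]]$W_cf))
})

test_that("model construction is reproducible bit-for-bit from the seed", {
  a <- dtnn_init(c(1, 6, 8), tiny_grid(), seed = 99)
  b <- dtnn_init(c(1, 6, 8), tiny_grid(), seed = 99)
  expect_identical(a, b)
  c <- dtnn_init(c(1, 6, 8), tiny_grid(), seed = 100)
  expect_false(identical(a$emb, c$emb))
})
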