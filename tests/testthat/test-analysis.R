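test_that("chemical potential grid matches pointwise probe energies", {
  p <- tiny_params()
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(4, seed = 51)
  res <- chemical_potential_grid(m, 1L, p, sc, origin = c(-0.5, -0.5, -0.5),
                                 spacing = 1.1, shape = c(2L, 2L, 2L))
  expect_identical(dim(res$values), c(2L, 2L, 2L))
  hist <- dtnn:::coeff_history(m, p)
  for (ix in 1:2) for (iy in 1:2) for (iz in 1:2) {
    r <- c(-0.5, -0.5, -0.5) + (c(ix, iy, iz) - 1) * 1.1
    expect_equal(res$values[ix, iy, iz],
                 probe_energy(m, 1L, r, p, sc, history = hist),
                 tolerance = 1e-10)
  }
})

test_that("probe grids never perturb the molecule and go flat beyond cutoff", {
  p <- tiny_params(cutoff = 2)
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(4, seed = 52)
  before <- molecular_energy(m, p, sc)
  far <- chemical_potential_grid(m, 8L, p, sc, origin = c(100, 100, 100),
                                 spacing = 0.5, shape = c(3L, 3L, 3L))
  after <- molecular_energy(m, p, sc)
  expect_identical(before$atomic, after$atomic)
  iso <- atomic_energies(embed(8L, p), p, sc)
  expect_equal(as.vector(far$values), rep(iso, 27), tolerance = 1e-12)
})

test_that("probe fields inherit molecular mirror symmetry", {
  p <- tiny_params()
  sc <- energy_scaler(0, 1)
  # homonuclear diatomic along z, grid symmetric about z = 0
  m <- molecule(c(8L, 8L), rbind(c(0, 0, -0.6), c(0, 0, 0.6)))
  res <- chemical_potential_grid(m, 1L, p, sc, origin = c(0.4, 0.4, -1),
                                 spacing = c(0.5, 0.5, 1), shape = c(2L, 2L, 3L))
  # z-planes 1 and 3 are mirror images
  expect_equal(res$values[, , 1], res$values[, , 3], tolerance = 1e-9)
})

test_that("isosurface field is an inverse-square atom sum", {
  m1 <- molecule(1L, matrix(0, 1, 3))
  expect_equal(isosurface_field(m1, c(1, 0, 0)), 1.0)
  # the 3.8 1/A^2 iso-level of a single atom sits at 1/sqrt(3.8) A
  r_iso <- 1 / sqrt(3.8)
  expect_equal(isosurface_field(m1, c(r_iso, 0, 0)), 3.8, tolerance = 1e-12)
  expect_equal(r_iso, 0.5130, tolerance = 1e-4)
  # superposition: two atoms, midpoint at distance d from each
  m2 <- molecule(c(6L, 6L), rbind(c(0, 0, -1.2), c(0, 0, 1.2)))
  expect_equal(isosurface_field(m2, c(0, 0, 0)), 2 / 1.2^2)
  expect_error(isosurface_field(m1, c(1e-8, 0, 0)), "coincides")
})

test_that("isosurface field decays as the inverse square far away", {
  m <- random_molecule(5, seed = 53)
  g10 <- isosurface_field(m, c(10, 0, 0))
  g20 <- isosurface_field(m, c(20, 0, 0))
  expect_equal(g10 / g20, 4, tolerance = 0.1)
  far_ratio <- isosurface_field(m, c(200, 0, 0)) /
    isosurface_field(m, c(400, 0, 0))
  expect_equal(far_ratio, 4, tolerance = 0.01)
})

test_that("cube export round-trips values, grid and geometry", {
  p <- tiny_params()
  sc <- energy_scaler(-3, 2)
  m <- molecule(c(1L, 8L), rbind(c(0, 0, 0), c(0, 0, 1.2)), id = "probe-mol")
  res <- chemical_potential_grid(m, 1L, p, sc, origin = c(-1, -1, -1),
                                 spacing = c(0.8, 0.9, 1.0),
                                 shape = c(2L, 2L, 2L))
  path <- withr::local_tempfile(fileext = ".cube")
  export_cube(res, path)
  lines <- readLines(path)
  expect_match(lines[3], "^\\s*2\\s")        # 2 atoms
  expect_match(lines[4], "^\\s*2\\s")        # 2 voxels along x
  back <- read_cube(path)
  expect_equal(back$values, res$values, tolerance = 1e-6)
  expect_equal(back$origin, res$origin, tolerance = 1e-6)
  expect_equal(back$spacing, res$spacing, tolerance = 1e-6)
  expect_identical(back$Z, m$Z)
  expect_equal(back$R, m$R, tolerance = 1e-5)
  bad <- res
  bad$shape <- c(2L, -1L, 2L)
  expect_error(export_cube(bad, path), "positive")
})

test_that("substructure energies partition the molecular energy", {
  p <- tiny_params()
  sc <- energy_scaler(-3, 2)
  m <- random_molecule(6, seed = 54)
  m$id <- "part"
  res <- molecular_energy(m, p, sc)
  all_atoms <- substructure_energy(m, res$atomic, 1:6)
  expect_equal(all_atoms$score, res$energy, tolerance = 1e-12)
  expect_identical(substructure_energy(m, res$atomic, integer(0))$score, 0)
  a <- substructure_energy(m, res$atomic, c(1, 3, 5))
  b <- substructure_energy(m, res$atomic, c(2, 4, 6))
  expect_equal(a$score + b$score, res$energy, tolerance = 1e-10)
  expect_error(substructure_energy(m, res$atomic, c(1, 1)), "duplicate")
  expect_error(substructure_energy(m, res$atomic, 7), "out of range")
})

test_that("substructure ranking is stable with lexicographic tie-breaks", {
  mk <- function(id, score) {
    structure(list(id = id, atom_indices = 1L, score = score),
              class = "substructure_score")
  }
  scores <- list(mk("a", 1), mk("b", 3), mk("c", 2))
  r <- rank_by_substructure(scores, 1)
  expect_identical(r$lowest[[1]]$id, "a")
  expect_identical(r$highest[[1]]$id, "b")
  # equal scores: order by id
  ties <- list(mk("z", 5), mk("m", 5), mk("a", 5))
  rt <- rank_by_substructure(ties, 3)
  expect_identical(vapply(rt$lowest, `[[`, character(1), "id"), c("a", "m", "z"))
  expect_identical(vapply(rt$highest, `[[`, character(1), "id"), c("z", "m", "a"))
  # k = n gives both lists in opposite order
  r_all <- rank_by_substructure(scores, 3)
  expect_identical(vapply(r_all$lowest, `[[`, character(1), "id"),
                   rev(vapply(r_all$highest, `[[`, character(1), "id")))
  expect_error(rank_by_substructure(scores, 4), "exceeds")
})

test_that("carbon six-rings are found from a bond list", {
  # benzene-like ring with hydrogens: C1..C6 ring, H on each C
  Z <- c(rep(6L, 6), rep(1L, 6))
  R <- matrix(rnorm(36), 12, 3)
  m <- molecule(Z, R)
  ring_bonds <- cbind(1:6, c(2:6, 1))
  ch_bonds <- cbind(1:6, 7:12)
  rings <- carbon_six_rings(m, rbind(ring_bonds, ch_bonds))
  expect_length(rings, 1L)
  expect_setequal(rings[[1]], 1:6)
  # no ring when a bond is missing
  rings2 <- carbon_six_rings(m, rbind(ring_bonds[-1, ], ch_bonds))
  expect_length(rings2, 0L)
})
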