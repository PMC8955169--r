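test_that("cell matrix reproduces the lattice parameters", {
  cell <- fibril_cell()
  h <- cell$h
  expect_equal(sqrt(sum(h[, 1]^2)), cell$a, tolerance = 1e-8)
  expect_equal(sqrt(sum(h[, 2]^2)), cell$b, tolerance = 1e-8)
  expect_equal(sqrt(sum(h[, 3]^2)), cell$c, tolerance = 1e-8)
  ang <- function(u, v) 180 / pi * acos(sum(u * v) /
                                          sqrt(sum(u^2) * sum(v^2)))
  expect_equal(ang(h[, 2], h[, 3]), cell$alpha, tolerance = 1e-8)
  expect_equal(ang(h[, 1], h[, 3]), cell$beta, tolerance = 1e-8)
  expect_equal(ang(h[, 1], h[, 2]), cell$gamma, tolerance = 1e-8)
  expect_gt(det(h), 0)
  expect_error(triclinic_cell(-1, 1, 1), "positive")
  expect_error(triclinic_cell(1, 1, 1, alpha = 200), "between 0 and 180")
})

test_that("fractional transforms invert each other", {
  cube <- ortho_cell(c(10, 10, 10))
  expect_equal(cart_to_frac(cube, c(5, 5, 5)), c(0.5, 0.5, 0.5))
  expect_equal(cart_to_frac(cube, c(12.5, 0, 0)), c(1.25, 0, 0))
  cell <- fibril_cell()
  p <- frac_to_cart(cell, c(0.3, 0.3, 0.3))
  expect_equal(cart_to_frac(cell, p), c(0.3, 0.3, 0.3), tolerance = 1e-9)
  f <- matrix(runif(60), 20)
  expect_equal(cart_to_frac(cell, frac_to_cart(cell, f)), f,
               tolerance = 1e-9)
})

test_that("minimum-image distances match the 27-image brute force", {
  cube <- ortho_cell(c(10, 10, 10))
  expect_equal(min_image_distance(cube, c(0.5, 0, 0), c(9.5, 0, 0)), 1.0)
  expect_equal(min_image_distance(cube, c(3, 4, 5), c(3, 4, 5)), 0)
  cell <- fibril_cell()
  set.seed(42)
  for (rep in 1:200) {
    p <- as.vector(frac_to_cart(cell, runif(3)))
    q <- as.vector(frac_to_cart(cell, runif(3)))
    expect_equal(min_image_distance(cell, p, q), brute_min_image(cell, p, q))
  }
})

test_that("per-atom wrap maps fractionals to [0,1) and is idempotent", {
  cell <- triclinic_cell(8, 9, 10, 85, 95, 100)
  set.seed(7)
  s <- bead_structure(frac_to_cart(cell, matrix(runif(90, -2, 3), 30)),
                      cell = cell)
  w <- wrap_structure(s, "atom")
  f <- cart_to_frac(cell, coords(w))
  expect_true(all(f >= 0 & f < 1))
  expect_equal(coords(wrap_structure(w, "atom")), coords(w))
  # the documented example: fractional (1.25, -0.1, 0.5) -> (0.25, 0.9, 0.5)
  s1 <- bead_structure(frac_to_cart(cell, c(1.25, -0.1, 0.5)), cell = cell)
  expect_equal(cart_to_frac(cell, coords(wrap_structure(s1))[1, ]),
               c(0.25, 0.9, 0.5), tolerance = 1e-12)
  expect_error(wrap_structure(bead_structure(c(1, 1, 1))), "cell")
})

test_that("per-molecule wrap moves molecules rigidly", {
  cell <- ortho_cell(c(10, 10, 10))
  # 2-atom molecule straddling the x face
  s <- bead_structure(rbind(c(9.7, 5, 5), c(10.4, 5, 5)), cell = cell,
                      bonds = cbind(i = 1, j = 2))
  w <- wrap_structure(s, "molecule")
  d_before <- sqrt(sum((coords(s)[1, ] - coords(s)[2, ])^2))
  d_after <- sqrt(sum((coords(w)[1, ] - coords(w)[2, ])^2))
  expect_equal(d_after, d_before, tolerance = 1e-12)
  shift <- coords(w) - coords(s)
  expect_equal(shift[1, ], shift[2, ], tolerance = 1e-12)
  ctr <- cart_to_frac(cell, colMeans(coords(w)))
  expect_true(all(ctr >= 0 & ctr < 1))
})

test_that("wrap preserves all minimum-image pair distances", {
  cell <- triclinic_cell(9, 11, 13, 80, 95, 105)
  set.seed(3)
  s <- bead_structure(frac_to_cart(cell, matrix(runif(45, -1, 2), 15)),
                      cell = cell)
  w <- wrap_structure(s, "atom")
  idx <- t(utils::combn(15, 2))
  d0 <- min_image_distance(cell, coords(s)[idx[, 1], ],
                           coords(s)[idx[, 2], ])
  d1 <- min_image_distance(cell, coords(w)[idx[, 1], ],
                           coords(w)[idx[, 2], ])
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("replicate_structure multiplies atoms, mass and cell", {
  tf <- make_toy_fibril(beads = 12)
  s <- tf$structure
  expect_identical(replicate_structure(s, 1, 1, 1), s)
  r <- replicate_structure(s, 3, 2, 1)
  expect_equal(natoms(r), 6 * natoms(s))
  expect_equal(total_mass(r), 6 * total_mass(s))
  expect_equal(r$cell$a, 3 * s$cell$a)
  expect_equal(r$cell$b, 2 * s$cell$b)
  expect_equal(nrow(r$bonds), 6 * nrow(s$bonds))
  # replication preserves composition per image
  expect_equal(element_counts(r), 6L * element_counts(s))
})

test_that("replicated periodic bonds stay periodic in the super-cell", {
  tf <- make_toy_fibril(beads = 12)
  r <- replicate_structure(tf$structure, 2, 2, 1)
  pc <- periodic_bond_counts(r)
  # z-crossing bonds: one per full-length chain per image
  expect_equal(unname(pc["z"]), 4 * tf$n_z_crossing)
  # every bond still has covalent length after re-targeting
  cl <- classify_periodic_bonds(r)
  expect_lt(max(cl$length), 2.0)
})

test_that("replicate-then-wrap equals wrap-then-replicate in composition", {
  tf <- make_toy_fibril(beads = 10)
  a <- wrap_structure(replicate_structure(tf$structure, 2, 1, 1), "atom")
  b <- replicate_structure(wrap_structure(tf$structure, "atom"), 2, 1, 1)
  expect_equal(natoms(a), natoms(b))
  expect_equal(element_counts(a), element_counts(b))
})
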