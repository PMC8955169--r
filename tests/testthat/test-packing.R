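# brute-force O(n^2) check of the packing distance contract
min_intermolecular <- function(packed, mol_of, cell) {
  xyz <- coords(packed)
  n <- nrow(xyz)
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- min_image_distance(cell, xyz[rep(i, n - i), , drop = FALSE],
                            xyz[(i + 1):n, , drop = FALSE],
                            periodic = c(FALSE, FALSE, TRUE))
    d <- d[mol_of[(i + 1):n] != mol_of[i]]
    if (length(d)) best <- min(best, min(d))
  }
  best
}

test_that("packed waters respect the tolerance (brute-force verified)", {
  base <- empty_structure(cell = ortho_cell(c(30, 30, 30)))
  task <- packing_task(make_water_template(), 10,
                       region_box(c(1, 1, 0), c(29, 29, 30)))
  pk <- pack_structures(base, task, seed = 42)
  expect_equal(natoms(pk), 30)
  mol_of <- rep(1:10, each = 3)
  expect_gte(min_intermolecular(pk, mol_of, pk$cell), 2.0)
})

test_that("count zero leaves the base unchanged", {
  tf <- make_toy_fibril(beads = 10)
  task <- packing_task(make_water_template(), 0,
                       region_box(c(0, 0, 0), c(5, 5, 5)))
  pk <- pack_structures(tf$structure, task, seed = 1)
  expect_equal(coords(pk), coords(tf$structure))
})

test_that("exclusion regions keep centres in the EFV at the 80/20 split", {
  simbox <- region_box(c(0, 0, 0), c(42, 42, 40), "SIMBOX")
  ifv <- region_box(c(12, 12, 0), c(30, 30, 40), "IFV")
  base <- empty_structure(cell = ortho_cell(c(42, 42, 40)))
  ha <- make_mineral_template()
  pk <- pack_structures(base, list(
    packing_task(ha, 8, simbox, exclusion = ifv, tolerance = 1.5),
    packing_task(ha, 2, ifv, tolerance = 1.5)), seed = 3)
  expect_equal(natoms(pk), 10 * 44)
  centres <- t(sapply(0:9, function(m)
    colMeans(coords(pk)[m * 44 + 1:44, ])))
  efv_centres <- centres[1:8, ]
  ifv_centres <- centres[9:10, ]
  expect_true(all(!in_region(ifv, efv_centres)))
  expect_true(all(in_region(simbox, efv_centres)))
  expect_true(all(in_region(ifv, ifv_centres)))
  # 8 of 10 in the EFV: the 80% partition
  expect_equal(mean(!in_region(ifv, centres)), 0.8)
})

test_that("packing is reproducible from the seed", {
  base <- empty_structure(cell = ortho_cell(c(25, 25, 25)))
  task <- packing_task(make_water_template(), 8,
                       region_box(c(1, 1, 0), c(24, 24, 25)))
  a <- pack_structures(base, task, seed = 7)
  b <- pack_structures(base, task, seed = 7)
  cc <- pack_structures(base, task, seed = 8)
  expect_identical(coords(a), coords(b))
  expect_false(identical(coords(a), coords(cc)))
})

test_that("an over-dense task fails loudly, not partially", {
  base <- empty_structure(cell = ortho_cell(c(12, 12, 12)))
  task <- packing_task(make_mineral_template(), 40,
                       region_box(c(1, 1, 1), c(11, 11, 11)),
                       max_attempts = 50)
  expect_error(pack_structures(base, task, seed = 1), "placed")
})

test_that("ten seeded tasks satisfy geometry and tolerance constraints", {
  water <- make_water_template()
  for (seed in 1:10) {
    box <- ortho_cell(c(24, 24, 20))
    base <- empty_structure(cell = box)
    excl <- region_box(c(8, 8, 0), c(16, 16, 20))
    pk <- pack_structures(base, list(
      packing_task(water, 6, region_box(c(1, 1, 0), c(23, 23, 20)),
                   exclusion = excl),
      packing_task(water, 3, excl)), seed = seed)
    mol_of <- rep(1:9, each = 3)
    expect_gte(min_intermolecular(pk, mol_of, box), 2.0)
    centres <- t(sapply(0:8, function(m)
      colMeans(coords(pk)[m * 3 + 1:3, ])))
    expect_true(all(!in_region(excl, centres[1:6, ])))
    expect_true(all(in_region(excl, centres[7:9, ])))
  }
})

test_that("grid insertion keeps queries exact while packing grows", {
  set.seed(5)
  cell <- ortho_cell(c(20, 20, 20))
  xyz <- matrix(runif(60, 0, 20), 20)
  g <- neighbor_grid(xyz, 3, cell = cell)
  more <- matrix(runif(30, 0, 20), 10)
  grid_insert(g, more)
  allxyz <- rbind(xyz, more)
  for (k in 1:10) {
    p <- runif(3, 0, 20)
    d <- min_image_distance(cell, matrix(p, 1), allxyz)
    expect_equal(grid_query(g, p), which(d <= 3))
  }
})
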