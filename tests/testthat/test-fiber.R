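test_that("extract_nanofiber removes lateral crossings, keeps axial ones", {
  for (seed in 1:3) {
    tf <- make_toy_fibril(seed = seed)
    before <- periodic_bond_counts(tf$structure)
    nano <- extract_nanofiber(tf$structure)
    after <- periodic_bond_counts(nano)
    expect_equal(unname(after["x"] + after["y"]), 0L)
    expect_equal(after["z"], before["z"])
    expect_equal(natoms(nano), natoms(tf$structure))
    expect_equal(nrow(nano$bonds), nrow(tf$structure$bonds))
  }
})

test_that("extract_nanofiber preserves the bond-length multiset", {
  tf <- make_toy_fibril(seed = 5)
  l0 <- sort(classify_periodic_bonds(tf$structure)$length)
  l1 <- sort(classify_periodic_bonds(extract_nanofiber(tf$structure))$length)
  expect_equal(l1, l0, tolerance = 1e-9)
})

test_that("extract_nanofiber is idempotent and identity on contiguous input", {
  tf <- make_toy_fibril()
  nano <- extract_nanofiber(tf$structure)
  again <- extract_nanofiber(nano)
  expect_equal(coords(again), coords(nano), tolerance = 1e-9)
})

test_that("build_fiber composes the bundle with conserved composition", {
  tf <- make_toy_fibril()
  nano <- extract_nanofiber(tf$structure)
  fm <- build_fiber(nano, nx = 2, ny = 2)
  expect_s3_class(fm, "fiber_model")
  expect_equal(element_counts(fm$structure), 4L * element_counts(nano))
  # IFV inside SIMBOX, positive EFV volume
  expect_true(all(fm$ifv$lower >= fm$simbox$lower - 1e-9))
  expect_true(all(fm$ifv$upper <= fm$simbox$upper + 1e-9))
  expect_gt(region_volume(fm$simbox), region_volume(fm$ifv))
  expect_error(build_fiber(nano, margins = c(0, 0)), "margins")
})

test_that("margins expand the simulation box beyond the fiber", {
  tf <- make_toy_fibril()
  nano <- extract_nanofiber(tf$structure)
  fm <- build_fiber(nano, nx = 1, ny = 1, margins = c(10, 10))
  xyz <- coords(fm$structure)
  span <- apply(xyz[, 1:2], 2, function(v) diff(range(v)))
  boxspan <- (fm$simbox$upper - fm$simbox$lower)[1:2]
  expect_equal(unname(boxspan - span), c(20, 20), tolerance = 1e-9)
})

test_that("cross-sections count 20 molecules in overlap and 16 in gap", {
  tf <- make_toy_fibril()
  nano <- extract_nanofiber(tf$structure)
  fm <- build_fiber(nano, nx = 2, ny = 2)
  zp <- zone_profile(fm)
  expect_equal(zp$overlap_count, 20L)
  expect_equal(zp$gap_count, 16L)
  expect_equal(cross_section_count(fm, zp$overlap_z), 20L)
  expect_equal(cross_section_count(fm, zp$gap_z), 16L)
})

test_that("gap count never exceeds overlap count along z", {
  tf <- make_toy_fibril(seed = 9)
  nano <- extract_nanofiber(tf$structure)
  fm <- build_fiber(nano, nx = 2, ny = 2)
  zp <- zone_profile(fm, nz = 40)
  expect_true(all(zp$profile$count <= zp$overlap_count))
  expect_true(all(zp$profile$count >= zp$gap_count))
  expect_lt(zp$gap_count, zp$overlap_count)
})

test_that("an empty slab counts zero molecules with a warning", {
  tf <- make_toy_fibril()
  fm <- build_fiber(extract_nanofiber(tf$structure), 1, 1,
                    margins = c(5, 5))
  expect_warning(n <- cross_section_count(fm, 1e4), "no atoms")
  expect_equal(n, 0L)
})

test_that("region boxes validate and measure volume", {
  expect_error(region_box(c(0, 0, 0), c(1, -1, 1)), "exceed")
  b <- region_box(c(0, 0, 0), c(2, 3, 4))
  expect_equal(region_volume(b), 24)
  expect_equal(in_region(b, rbind(c(1, 1, 1), c(3, 1, 1))), c(TRUE, FALSE))
})
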