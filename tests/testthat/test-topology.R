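test_that("infer_bonds applies the covalent-radius heuristic", {
  # water geometry: two O-H bonds, no H-H
  w <- make_water_template()
  w$cell <- ortho_cell(c(20, 20, 20))
  wb <- infer_bonds(w)
  expect_equal(nrow(wb$bonds), 2)
  expect_true(all(wb$bonds[, "i"] == 1))
  # two argon-like atoms 4 A apart: no bonds
  ar <- mol_structure(data.frame(
    serial = 1:2, name = "AR", element = "Ar", resname = "AR",
    resid = 1:2, chain = "A", x = c(0, 4), y = 0, z = 0),
    cell = ortho_cell(c(20, 20, 20)))
  expect_equal(nrow(infer_bonds(ar)$bonds), 0)
})

test_that("infer_bonds reproduces the generator's ground-truth bonds", {
  for (seed in 1:3) {
    tf <- make_toy_fibril(beads = 30, seed = seed)
    inferred <- infer_bonds(tf$structure)
    key <- function(b) paste(b[, "i"], b[, "j"])
    expect_setequal(key(inferred$bonds), key(tf$bonds))
    # and the recovered image shifts agree with the ground truth
    ord1 <- order(inferred$bonds[, "i"], inferred$bonds[, "j"])
    ord2 <- order(tf$bonds[, "i"], tf$bonds[, "j"])
    expect_equal(unname(inferred$bonds[ord1, c("sx", "sy", "sz")]),
                 unname(tf$bonds[ord2, c("sx", "sy", "sz")]))
  }
})

test_that("infer_bonds flags clashes instead of guessing", {
  xyz <- rbind(c(0, 0, 0), as.matrix(expand.grid(x = c(-.7, .7),
                                                 y = c(-.7, .7),
                                                 z = c(-.7, .7))),
               c(0, 0, 1), c(0, 1, 0))
  s <- bead_structure(xyz, cell = ortho_cell(c(30, 30, 30)))
  expect_error(infer_bonds(s), "clash")
})

test_that("molecules partitions atoms deterministically", {
  # 3 disjoint waters
  w <- make_water_template()
  cell <- ortho_cell(c(30, 30, 30))
  s <- w
  s$cell <- cell
  for (k in 1:2) {
    w2 <- w
    coords(w2) <- sweep(coords(w), 2, c(8 * k, 0, 0), "+")
    s <- merge_structures(s, w2)
  }
  m <- molecules(s)
  expect_length(m, 3)
  expect_equal(lengths(m), rep(3L, 3))
  expect_equal(m[[1]], 1:3)

  # one periodic bond joins two fragments across z into one molecule
  s2 <- bead_structure(rbind(c(5, 5, 1), c(5, 5, 29)),
                       cell = ortho_cell(c(10, 10, 30)),
                       bonds = cbind(i = 2, j = 1, sx = 0, sy = 0, sz = 1))
  expect_length(molecules(s2), 1)

  # generator ground truth
  tf <- make_toy_fibril()
  expect_equal(molecule_count <- length(molecules(tf$structure)), 5)
  mid <- integer(natoms(tf$structure))
  for (k in seq_along(molecules(tf$structure)))
    mid[molecules(tf$structure)[[k]]] <- k
  expect_equal(mid, tf$molecule_id)
})

test_that("molecules() is invariant under wrap and replicate-by-1", {
  tf <- make_toy_fibril(beads = 15)
  m0 <- molecules(tf$structure)
  expect_equal(molecules(wrap_structure(tf$structure, "atom")), m0)
  expect_equal(molecules(replicate_structure(tf$structure, 1, 1, 1)), m0)
})

test_that("classify_periodic_bonds finds minimal image shifts", {
  cell <- ortho_cell(c(10, 10, 10))
  s <- bead_structure(rbind(c(0.2, 5, 5), c(9.8, 5, 5)), cell = cell,
                      bonds = cbind(i = 1, j = 2))
  cl <- classify_periodic_bonds(s)
  expect_equal(cl$sx, -1L)
  expect_equal(cl$length, 0.4, tolerance = 1e-12)

  # fully interior molecule: all shifts zero
  w <- make_water_template()
  w$cell <- cell
  coords(w) <- sweep(coords(w), 2, c(5, 5, 5), "+")
  cl2 <- classify_periodic_bonds(w)
  expect_true(all(cl2[, c("sx", "sy", "sz")] == 0))

  # generator ground truth: known z-crossing count
  tf <- make_toy_fibril()
  cl3 <- classify_periodic_bonds(tf$structure)
  expect_equal(sum(cl3$sz != 0), tf$n_z_crossing)
  expect_equal(sum(cl3$sx != 0 | cl3$sy != 0), tf$n_xy_crossing)

  # implausibly long bond draws a warning
  sl <- bead_structure(rbind(c(1, 5, 5), c(5, 5, 5)), cell = cell,
                       bonds = cbind(i = 1, j = 2))
  expect_warning(classify_periodic_bonds(sl), "exceed")
})

test_that("bond classifications can be dumped as TSV", {
  tf <- make_toy_fibril(beads = 10)
  cl <- classify_periodic_bonds(tf$structure)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_bond_classification(cl, p)
  back <- utils::read.delim(p)
  expect_equal(nrow(back), nrow(cl))
  expect_equal(back$sz, cl$sz)
})

test_that("neighbor grid queries equal brute force", {
  set.seed(11)
  cell <- triclinic_cell(18, 22, 25, 85, 92, 110)
  xyz <- frac_to_cart(cell, matrix(runif(3000), 1000))
  g <- neighbor_grid(xyz, cutoff = 4.5, cell = cell)
  for (q in 1:50) {
    p <- as.vector(frac_to_cart(cell, runif(3)))
    d <- min_image_distance(cell, matrix(p, 1), xyz)
    expect_equal(grid_query(g, p), which(d <= 4.5))
  }
  # empty structure and oversized-cutoff degradation
  ge <- neighbor_grid(matrix(numeric(0), 0, 3), 3, cell = cell)
  expect_equal(grid_query(ge, c(1, 1, 1)), integer(0))
  gall <- neighbor_grid(xyz, cutoff = 40, cell = cell)
  p <- c(5, 5, 5)
  d <- min_image_distance(cell, matrix(p, 1), xyz)
  expect_equal(grid_query(gall, p, 40), which(d <= 40))
})
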