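test_that("the strain schedule follows the constant-rate closed form", {
  sch <- strain_schedule(677.9, 1e-5, 30000)
  expect_equal(box_length(sch, 0), 677.9)
  # 30 ps at 1e-5/fs extends the box to 1.3 L0: 30% engineering strain
  expect_equal(box_length(sch, 30000), 1.3 * 677.9)
  expect_equal(engineering_strain(box_length(sch, 30000), 677.9), 0.3)
  expect_equal(box_length(strain_schedule(100, 0, 1000), 500), 100)
  expect_error(box_length(sch, -1), "non-negative")
  expect_error(strain_schedule(-5, 1e-5, 10), "positive")
})

test_that("engineering strain is the schedule's algebraic inverse", {
  sch <- strain_schedule(250, 3e-5, 20000)
  ts <- seq(0, 20000, by = 500)
  expect_equal(engineering_strain(box_length(sch, ts), 250),
               sch$rate * ts, tolerance = 1e-12)
  expect_equal(engineering_strain(100, 100), 0)
})

test_that("virial pressure: single free particle closed form", {
  m <- 39.95; vx <- 0.01; vol <- 1000
  p <- virial_pressure(m, matrix(c(vx, 0, 0), 1), vol, units = "GPa")
  expect_equal(p[1, 1], m * vx^2 / vol * 1e7 / 4184 *
                 bonefiber:::.KCAL_A3_TO_GPA)
  expect_equal(p[2, 2], 0)
  expect_equal(p[1, 2], 0)
})

test_that("zero-force gas pressure matches N kB T / V", {
  set.seed(21)
  n <- 500; m <- rep(18, n); vol <- 8000
  temp <- 310
  sd <- sqrt(0.0019872041 * temp / (m * (1e7 / 4184)))
  v <- matrix(stats::rnorm(3 * n), n, 3) * sd
  p <- virial_pressure(m, v, vol, units = "atm")
  ideal <- n * 0.0019872041 * temp / vol * bonefiber:::.KCAL_A3_TO_ATM
  # trace/3 fluctuates with se = ideal * sqrt(2 / (3 n))
  se <- ideal * sqrt(2 / (3 * n))
  expect_lt(abs(mean(diag(p)) - ideal), 3 * se)
  expect_equal(p, t(p))
})

test_that("stretched-spring pressure matches the hand calculation", {
  # two particles joined by a spring along z, at rest, stretched by 0.5 A
  k <- 80; r0 <- 2; r <- 2.5; vol <- 1234.5
  fmag <- k * (r - r0)                   # restoring force magnitude
  pair_r <- matrix(c(0, 0, r), 1)        # displacement i -> j
  pair_f <- matrix(c(0, 0, -fmag), 1)    # force on j (towards i)
  p <- virial_pressure(c(1, 1), NULL, vol, pair_r = pair_r,
                       pair_f = pair_f, units = "GPa")
  expect_equal(p[3, 3], -r * fmag / vol * bonefiber:::.KCAL_A3_TO_GPA,
               tolerance = 1e-10)
  expect_gt(stress_zz(p), 0)             # tension reported positive
})

test_that("modulus fit recovers an exact line with zero stderr", {
  s <- stress_strain_series(seq(0, 0.3, by = 0.001),
                            5 * seq(0, 0.3, by = 0.001))
  fit <- fit_young_modulus(s)
  expect_equal(fit$E, 5)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_lt(fit$stderr, 1e-10)
  expect_error(fit_young_modulus(s, window = c(0.8, 0.9)), "inside")
})

test_that("noisy modulus fits recover the slope within 3 stderr", {
  s <- make_stress_strain(2, noise = 0.01, n = 600, seed = 4)
  fit <- fit_young_modulus(s)
  expect_lt(abs(fit$E - 2), 3 * fit$stderr)
})

test_that("the fit is stable under subsampling within the window", {
  s <- make_stress_strain(7, noise = 0.005, n = 2000, seed = 6)
  f1 <- fit_young_modulus(s)
  sub <- stress_strain_series(s$strain[seq(1, 2000, by = 4)],
                              s$stress[seq(1, 2000, by = 4)])
  f2 <- fit_young_modulus(sub)
  expect_lt(abs(f1$E - f2$E), 3 * (f1$stderr + f2$stderr))
})

test_that("block averaging shrinks the series and keeps the slope", {
  s <- make_stress_strain(3, noise = 0.02, n = 900, seed = 8)
  b <- block_average(s, 9)
  expect_equal(nrow(b), 100)
  expect_lt(abs(fit_young_modulus(b)$E - 3), 0.2)
})

test_that("rmsd measures translations and vanishes after superposition", {
  tf <- make_toy_fibril(beads = 12)
  s <- tf$structure
  expect_equal(rmsd(s, s), 0)
  s2 <- s
  coords(s2) <- sweep(coords(s), 2, c(3, 4, 0), "+")
  expect_equal(rmsd(s, s2), 5.0, tolerance = 1e-9)
  expect_equal(rmsd(s, s2, superpose = TRUE), 0, tolerance = 1e-6)
  s3 <- subset_atoms(s, 1:10)
  expect_error(rmsd(s, s3), "differ")
})
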