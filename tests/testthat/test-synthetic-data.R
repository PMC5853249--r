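test_that("jitter-free lattice matches the enumeration oracle", {
  reg <- cell_region(10000, 10000)
  pap <- generate_papilla_lattice(reg, spacing = 1500, jitter_sd = 0)
  expect_equal(length(pap), 36L)  # 6 x 6 grid of full 1.5 um cells
  expect_setequal(unique(pap$x), (seq_len(6) - 0.5) * 1500)
  expect_setequal(unique(pap$y), (seq_len(6) - 0.5) * 1500)

  expect_error(generate_papilla_lattice(cell_region(1000, 1000),
                                        spacing = 1500), "too small")
  expect_error(generate_papilla_lattice(reg, spacing = 300, diameter = 380),
               "exceed")
})

test_that("large-window lattice density approaches 1/spacing^2", {
  reg <- cell_region(50000, 50000)  # 50 x 50 um
  pap <- generate_papilla_lattice(reg, spacing = 1500)
  density_mm2 <- length(pap) / (50e-3 * 50e-3)  # per mm^2
  analytic <- 1 / (1.5e-3)^2                    # 4.44e5 mm^-2
  expect_lt(abs(density_mm2 - analytic) / analytic, 0.05)
})

test_that("jittered lattice stays in the window and is seed-deterministic", {
  reg <- cell_region(10000, 10000)
  a <- generate_papilla_lattice(reg, jitter_sd = 150, seed = 21)
  b <- generate_papilla_lattice(reg, jitter_sd = 150, seed = 21)
  expect_identical(a, b)
  expect_true(all(a$x >= 0 & a$x <= 10000 & a$y >= 0 & a$y <= 10000))
  c <- generate_papilla_lattice(reg, jitter_sd = 150, seed = 22)
  expect_false(identical(a$x, c$x))
})

test_that("attached bundles satisfy the association criterion by construction", {
  reg <- cell_region(10000, 10000)
  pap <- generate_papilla_lattice(reg, jitter_sd = 100, seed = 3)
  bnd <- generate_bundles(pap, reg, n_bundles = 40, assoc_fraction = 1,
                          seed = 4)
  expect_equal(length(bnd), 40L)
  expect_equal(fraction_bundles_associated(pap, bnd), 1)
  expect_true(all(bundle_lengths(bnd) > 0))
  expect_true(all(bnd$segments$diameter > 0))

  expect_error(generate_bundles(papilla_pattern(numeric(), numeric(), reg),
                                reg, 5, assoc_fraction = 0.5), "non-empty")
})

test_that("unattached bundles are distributed as the null placement", {
  reg <- cell_region(10000, 10000)
  pap <- generate_papilla_lattice(reg, jitter_sd = 0)
  n <- 10000
  gen <- generate_bundles(pap, reg, n_bundles = n, assoc_fraction = 0,
                          length_sd = 0, seed = 41)
  ref <- place_random_bundles(reg, rep(1100, n), seed = 42)
  d_gen <- distance_to_nearest_papilla(gen$segments$x1, gen$segments$y1, pap)
  d_ref <- distance_to_nearest_papilla(ref$segments$x1, ref$segments$y1, pap)
  ks <- suppressWarnings(ks.test(d_gen, d_ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("noise-free fluorescence generation reproduces the true means exactly", {
  tm <- data.frame(treatment = rep(c("15h Control", "BFA"), each = 3),
                   region = rep(c("outer_periclinal", "anticlinal",
                                  "inner_periclinal"), 2),
                   mean = c(400, 40, 30, 15, 15, 17))
  raw <- generate_fluorescence_dataset(tm, cell_sd = 0, seed = 8)
  expect_equal(nrow(raw), 6 * 25 * 4)
  summ <- summarize_fluorescence(raw)
  merged <- merge(summ, tm, by = c("treatment", "region"))
  expect_equal(merged$mean.x, merged$mean.y)
  expect_true(all(summ$se == 0))
  expect_true(all(summ$n == 4L))
})

test_that("correcting a treatment against an identical baseline yields nulls", {
  tm <- data.frame(treatment = rep(c("X", "BFA"), each = 3),
                   region = rep(c("outer_periclinal", "anticlinal",
                                  "inner_periclinal"), 2),
                   mean = rep(c(100, 50, 30), 2))
  set.seed(55)
  cover <- replicate(500, {
    raw <- generate_fluorescence_dataset(tm, cell_sd = 20)
    summ <- summarize_fluorescence(raw)
    cor <- bfa_correct_table(summ)
    # per corrected regional mean: |difference| within 3 SE
    mean(abs(cor$raw_mean) < 3 * cor$se)
  })
  expect_gte(mean(cover), 0.95)
})

test_that("a 9-h-control-like configuration recovers its target total", {
  # baseline-plus-signal design: corrected regional means 513 / 35 / 0
  bfa <- c(outer_periclinal = 60, anticlinal = 25, inner_periclinal = 20)
  signal <- c(outer_periclinal = 513, anticlinal = 35, inner_periclinal = 0)
  tm <- data.frame(treatment = rep(c("9h Control", "BFA"), each = 3),
                   region = rep(names(bfa), 2),
                   mean = c(bfa + signal, bfa))
  raw <- generate_fluorescence_dataset(tm, cell_sd = 25, seed = 14)
  cor <- bfa_correct_table(summarize_fluorescence(raw))
  tot <- table_totals(cor)
  expect_lt(abs(tot$mean - 548), 2 * tot$se + 1e-12)
})

test_that("time courses encode the lag and respect bounds", {
  tc0 <- generate_timecourse(lag_h = 0, noise_sd = 0)
  expect_equal(tc0$pct_remodelled, tc0$pct_papillae)

  tc1 <- generate_timecourse(lag_h = 1, noise_sd = 0)
  fit <- lagged_r2(tc1$time_h, tc1$pct_remodelled, tc1$pct_papillae)
  expect_equal(fit$lag, 1)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  tcn <- generate_timecourse(lag_h = 1, noise_sd = 5, seed = 2)
  expect_true(all(tcn$pct_remodelled >= 0 & tcn$pct_remodelled <= 100))
  expect_identical(tcn, generate_timecourse(lag_h = 1, noise_sd = 5, seed = 2))
})
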