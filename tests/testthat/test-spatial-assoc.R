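test_that("association counting follows the strict <400 nm endpoint rule", {
  reg <- cell_region(6000, 2000)
  pap <- papilla_pattern(c(0, 2000, 4000), c(0, 0, 0), reg)

  # no linear bundles: zero associated, statistic still valid
  expect_equal(count_associated_papillae(pap, bundle_set(region = reg))$n_associated, 0L)

  # coincident endpoint: distance 0 associates
  one <- bundle_set(2000, 0, 2900, 0, 150, "linear", reg)
  expect_true(count_associated_papillae(pap, one)$associated[2])

  # nearest end distances 350, 550 and sqrt(395^2 + 5^2) ~ 395.03:
  # papillae 1 and 3 associated, papilla 2 not
  bnd <- bundle_set(x1 = c(350, 4395), y1 = c(0, 5),
                    x2 = c(1450, 5000), y2 = c(0, 900),
                    diameter = 150, region = reg)
  res <- count_associated_papillae(pap, bnd)
  expect_equal(res$n_associated, 2L)
  expect_equal(res$associated, c(TRUE, FALSE, TRUE))

  # the threshold is strict: an end at exactly 400 nm does not associate
  exact <- bundle_set(400, 0, 1300, 0, 150, "linear", reg)
  expect_false(count_associated_papillae(papilla_pattern(0, 0, reg),
                                         exact)$associated[1])
  expect_true(count_associated_papillae(papilla_pattern(0, 0, reg), exact,
                                        threshold = 400.001)$associated[1])

  # circular bundles have no ends
  ring <- bundle_set(2000, 0, 380, NA, 150, "circular", reg)
  expect_equal(count_associated_papillae(pap, ring)$n_associated, 0L)

  expect_error(count_associated_papillae(
    papilla_pattern(numeric(), numeric(), reg), bnd), "undefined")
})

test_that("association counts match a brute-force distance scan on random instances", {
  reg <- cell_region(8000, 6000)
  set.seed(402)
  for (i in 1:200) {
    inst <- random_instance(reg)
    expect_equal(count_associated_papillae(inst$papillae, inst$bundles)$n_associated,
                 brute_force_assoc(inst$papillae, inst$bundles))
  }
})

test_that("random placement preserves dimensions, containment and determinism", {
  reg <- cell_region(10000, 10000)
  empty <- place_random_bundles(reg, numeric())
  expect_equal(length(empty), 0L)

  b1 <- place_random_bundles(reg, rep(1100, 20), 150, seed = 5)
  expect_equal(length(b1), 20L)
  expect_equal(bundle_lengths(b1), rep(1100, 20), tolerance = 1e-9)
  seg <- b1$segments
  expect_true(all(seg$x1 >= 0 & seg$x1 <= 10000 & seg$x2 >= 0 &
                    seg$x2 <= 10000 & seg$y1 >= 0 & seg$y1 <= 10000 &
                    seg$y2 >= 0 & seg$y2 <= 10000))
  b2 <- place_random_bundles(reg, rep(1100, 20), 150, seed = 5)
  expect_identical(b1, b2)

  expect_error(place_random_bundles(cell_region(1000, 5000), 1000),
               "shortest window side")
})

test_that("null placement matches the accept/reject conditioned-uniform oracle", {
  w <- h <- 10000; len <- 1100
  n <- 10000
  set.seed(31)
  mine <- place_random_bundles(cell_region(w, h), rep(len, n))$segments
  mid_x <- (mine$x1 + mine$x2) / 2
  oracle <- replicate(n, naive_place_one(w, h, len)["mx"])
  ks <- suppressWarnings(ks.test(mid_x, oracle))
  expect_gt(ks$p.value, 0.01)
})

test_that("Monte Carlo p-values behave at the degenerate bounds", {
  reg <- cell_region(10000, 10000)
  # observed 0% association: every null percent >= 0, so p = 1
  pap <- papilla_pattern(5000, 5000, reg)
  far <- bundle_set(0, 0, 1100, 0, 150, "linear", reg)
  r <- monte_carlo_test(pap, far, n_sims = 50, seed = 1)
  expect_equal(r$percent_observed, 0)
  expect_equal(r$p_value, 1)

  # window so small that any placement associates every papilla
  tiny <- cell_region(1000, 1000)
  pap2 <- papilla_pattern(c(400, 600), c(500, 500), tiny)
  b2 <- bundle_set(100, 100, 800, 800, 150, "linear", tiny)
  r2 <- monte_carlo_test(pap2, b2, n_sims = 50, threshold = 2000, seed = 2)
  expect_equal(r2$percent_observed, 100)
  expect_true(all(r2$null_percents == 100))
  expect_equal(r2$p_value, 1)
})

test_that("the test is deterministic under a seed and p is monotone in the observed percent", {
  reg <- cell_region(10000, 10000)
  cell <- generate_cell(reg, n_bundles = 20, assoc_fraction = 0.8,
                        n_papillae = 15, seed = 9)
  a <- monte_carlo_test(cell$papillae, cell$bundles, n_sims = 300, seed = 17)
  b <- monte_carlo_test(cell$papillae, cell$bundles, n_sims = 300, seed = 17)
  expect_identical(a, b)

  # same bundle dimensions, same seed => identical null distribution;
  # a weakly associated observation cannot get a smaller p-value
  lens <- bundle_lengths(cell$bundles)
  weak <- place_random_bundles(reg, lens, seed = 3)
  pw <- monte_carlo_test(cell$papillae, weak, n_sims = 300, seed = 17)
  expect_identical(pw$null_percents, a$null_percents)
  expect_lte(pw$percent_observed, a$percent_observed)
  expect_gte(pw$p_value, a$p_value)

  # pseudo-count variant reports (k+1)/(n+1)
  pc <- monte_carlo_test(cell$papillae, cell$bundles, n_sims = 300,
                         seed = 17, pseudo_count = TRUE)
  k <- sum(a$null_percents >= a$percent_observed)
  expect_equal(pc$p_value, (k + 1) / 301)
})

test_that("cohort aggregation reports mean, SE and p-value display strings", {
  expect_error(aggregate_cells(list()), "non-empty")

  reg <- cell_region(10000, 10000)
  mk <- function(pct_target) {
    # construct a result with a prescribed observed percent
    n_pap <- 10
    pap <- papilla_pattern(seq(500, 9500, length.out = n_pap),
                           rep(5000, n_pap), reg)
    k <- round(pct_target / 10)
    if (k > 0) {
      # far endpoints point away from the papilla row so each bundle
      # associates exactly one papilla
      bnd <- bundle_set(pap$x[seq_len(k)], pap$y[seq_len(k)],
                        pap$x[seq_len(k)], pap$y[seq_len(k)] + 900,
                        150, "linear", reg)
    } else {
      bnd <- bundle_set(region = reg)
    }
    monte_carlo_test(pap, bnd, n_sims = 100, seed = 4)
  }
  one <- aggregate_cells(list(mk(60)))
  expect_equal(one$mean_percent, 60)
  expect_equal(one$se_percent, 0)

  two <- aggregate_cells(list(a = mk(50), b = mk(70)))
  expect_equal(two$mean_percent, 60)
  expect_equal(two$se_percent, 10)  # sd 14.142... / sqrt(2)

  # p of exactly 0 renders as the resolution bound
  expect_equal(format_p_value(0, 1000), "< 0.001")
  expect_equal(format_p_value(0.004, 1000), "0.004")
})

test_that("assoc_test_cells reproduces a whole cohort from one seed", {
  reg <- cell_region(10000, 10000)
  set.seed(23)
  cells <- lapply(1:3, function(i) {
    generate_cell(reg, n_bundles = 15, assoc_fraction = 0.7, n_papillae = 12)
  })
  names(cells) <- paste0("c", 1:3)
  co1 <- assoc_test_cells(cells, n_sims = 100, seed = 99)
  co2 <- assoc_test_cells(cells, n_sims = 100, seed = 99)
  expect_identical(co1$table, co2$table)
  expect_equal(co1$n_cells, 3L)
})
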