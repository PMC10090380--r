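fake_records <- function(n_pis, norm_rf = seq_along(n_pis) / length(n_pis),
                         ids = sprintf("g%05d", seq_along(n_pis))) {
  data.frame(gene_id = ids, norm_rf = norm_rf, n_pis = as.integer(n_pis),
             excluded = FALSE, stringsAsFactors = FALSE)
}

test_that("bin_by_pis sorts by PIS and cuts equal-sized bins", {
  set.seed(8)
  recs <- fake_records(sample(1:5000, 3000, replace = TRUE))
  bins <- bin_by_pis(recs, bin_size = 1000)
  expect_equal(lengths(lapply(bins, function(b) b$gene_id)),
               c(1000L, 1000L, 1000L))
  all_pis <- unlist(lapply(bins, function(b) b$n_pis))
  expect_false(is.unsorted(all_pis))

  bins2 <- bin_by_pis(fake_records(sample(1:5000, 2400, TRUE)), 1000)
  expect_equal(vapply(bins2, nrow, integer(1)), c(1000L, 1400L))

  bins2k <- bin_by_pis(fake_records(sample(1:5000, 2400, TRUE)), 1000,
                       remainder_policy = "keep")
  expect_equal(vapply(bins2k, nrow, integer(1)), c(1000L, 1000L, 400L))

  # remainder of at least half a bin stays separate under "merge"
  bins3 <- bin_by_pis(fake_records(sample(1:5000, 2600, TRUE)), 1000)
  expect_equal(vapply(bins3, nrow, integer(1)), c(1000L, 1000L, 600L))

  expect_length(bin_by_pis(fake_records(sample(1:50, 700, TRUE)), 1000), 1)
  expect_error(bin_by_pis(fake_records(1L)[0, ], 1000), "no records")
  expect_error(bin_by_pis(fake_records(c(0L, 5L)), 1000), "n_pis")
})

test_that("PIS ties are broken stably by gene_id", {
  recs <- fake_records(rep(10L, 6), norm_rf = c(.1, .2, .3, .4, .5, .6),
                       ids = c("z", "a", "m", "b", "y", "c"))
  bin <- bin_by_pis(recs, bin_size = 10)[[1]]
  expect_equal(bin$gene_id, c("a", "b", "c", "m", "y", "z"))
})

test_that("select_lower_quantile keeps ceil(q*n) smallest RF values", {
  set.seed(21)
  vals <- sample(seq(0.001, 1, length.out = 1000))
  bin <- fake_records(rep(50L, 1000), norm_rf = vals)
  sel <- select_lower_quantile(bin, 0.05)
  expect_equal(nrow(sel), 50L)
  expect_setequal(sel$norm_rf, sort(vals)[1:50])

  sel40 <- select_lower_quantile(fake_records(rep(5L, 40)), 0.05)
  expect_equal(nrow(sel40), 2L)

  ties <- fake_records(rep(3L, 10), norm_rf = rep(0.4, 10))
  sel1 <- select_lower_quantile(ties, 0.05)
  expect_equal(nrow(sel1), 1L)
  expect_equal(sel1$gene_id, ties$gene_id[1])  # first in stable order
})

test_that("fit_baseline recovers a noiseless generating line", {
  pts <- data.frame(n_pis = c(10L, 100L, 1000L),
                    norm_rf = -0.2 * log10(c(10, 100, 1000)) + 0.9)
  m <- fit_baseline(pts)
  expect_equal(m$a, -0.2, tolerance = 1e-10)
  expect_equal(m$b, 0.9, tolerance = 1e-10)

  two <- fit_baseline(data.frame(n_pis = c(10L, 1000L),
                                 norm_rf = c(0.7, 0.3)))
  expect_equal(two$a, -0.2, tolerance = 1e-10)
  expect_equal(two$b, 0.9, tolerance = 1e-10)

  expect_error(fit_baseline(data.frame(n_pis = c(50L, 50L),
                                       norm_rf = c(0.1, 0.2))),
               "unidentifiable")
})

test_that("normalize_rf divides by the fitted baseline with an eps guard", {
  m <- structure(list(a = -0.2, b = 0.9, bin_size = NA, quantile = NA,
                      n_points_fit = 2L), class = "pis_baseline")
  expect_equal(normalize_rf(0.25, 100L, m), 0.5)   # baseline 0.5
  expect_equal(normalize_rf(0.5, 100L, m), 1)      # RF equal to baseline

  bad <- structure(list(a = -0.5, b = 0.4, bin_size = NA, quantile = NA,
                        n_points_fit = 2L), class = "pis_baseline")
  expect_warning(out <- normalize_rf(c(0.2, 0.2), c(1L, 1000L), bad),
                 "non-positive")
  expect_equal(out[1], 0.5)     # baseline b = 0.4 at n_pis = 1
  expect_true(is.na(out[2]))    # baseline 0.4 - 1.5 = -1.1: flagged
})

test_that("RF' increases in RF and in PIS count for a negative slope", {
  m <- structure(list(a = -0.15, b = 0.8, bin_size = NA, quantile = NA,
                      n_points_fit = 2L), class = "pis_baseline")
  rf_grid <- seq(0.05, 0.95, by = 0.05)
  out <- normalize_rf(rf_grid, rep(200L, length(rf_grid)), m)
  expect_true(all(diff(out) > 0))
  pis_grid <- as.integer(round(10^seq(1, 4, by = 0.25)))
  out2 <- normalize_rf(rep(0.5, length(pis_grid)), pis_grid, m)
  expect_true(all(diff(out2) > 0))
})

test_that("bin->select->fit recovers generating parameters from noisy data", {
  set.seed(314)
  n <- 20000
  n_pis <- as.integer(round(10^runif(n, 1, 4)))
  rf <- pmax(0, -0.15 * log10(n_pis) + 0.8) + abs(rnorm(n, 0, 0.1))
  recs <- fake_records(n_pis, norm_rf = rf)
  m <- fit_pis_baseline(recs, bin_size = 1000, quantile = 0.05)
  expect_lt(abs(m$a - (-0.15)), 0.03)  # scaled-down run (20k points);
  expect_lt(abs(m$b - 0.8), 0.05)      # the full 50k case is exercised
  expect_equal(m$n_points_fit, 1000L)  # elsewhere. 20 bins x 50 points.
})
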