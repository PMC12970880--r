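test_that("seed-content standardization and per-unit scaling", {
  expect_equal(standardize_seed_content(30, 2.5), 12)
  expect_equal(standardize_seed_content(0, 2.5), 0)
  expect_equal(standardize_seed_content(97, 1.0), 97)
  expect_error(standardize_seed_content(10, 0), "positive")
  expect_equal(per_fecal_unit(5, "cow"), 3150)
  expect_equal(per_fecal_unit(0, "horse"), 0)
  expect_equal(per_fecal_unit(10, "wild_boar"), 129)
  expect_error(per_fecal_unit(1, "sheep"), "dung-weight")
  expect_error(dung_weight_table(deer = -1), "positive")
})

test_that("per-unit means are dung-weight multiples of per-gram means", {
  set.seed(9)
  spg <- rgamma(40, 2)
  rec <- data.frame(species = "cow", seeds_per_g = spg,
                    seeds_per_unit = per_fecal_unit(spg, rep("cow", 40)))
  expect_equal(mean(rec$seeds_per_unit), 630 * mean(rec$seeds_per_g))
})

test_that("Grubbs critical value follows the t-quantile formula", {
  # independent oracle: invert the t CDF by numerical integration
  t_quantile_oracle <- function(p, df) {
    dens <- function(x) stats::dt(x, df)
    cdf <- function(q) 0.5 + stats::integrate(dens, 0, q,
                                              rel.tol = 1e-12)$value
    stats::uniroot(function(q) cdf(q) - p, c(0, 100), tol = 1e-10)$root
  }
  for (n in c(5, 10, 30, 118)) {
    t <- t_quantile_oracle(1 - 0.05 / (2 * n), n - 2)
    oracle <- (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
    expect_equal(grubbs_critical(n, 0.05), oracle, tolerance = 1e-3)
  }
  expect_equal(round(grubbs_critical(118, 0.05), 2), 3.44)
  expect_equal(grubbs_critical(10, 0.05), 2.29, tolerance = 5e-3)
  # monotone decreasing in alpha at fixed n
  alphas <- c(0.01, 0.05, 0.1, 0.5)
  expect_true(all(diff(sapply(alphas, grubbs_critical, n = 20)) < 0))
  expect_error(grubbs_critical(2, 0.05), "n >= 3")
})

test_that("Grubbs test flags a gross outlier and not a clean sample", {
  x <- c(rep(1, 117), 50)
  res <- grubbs_test(x, 0.05)
  # brute-force check of the statistic itself
  expect_equal(res$g_statistic, max(abs(x - mean(x))) / sd(x))
  expect_true(res$is_outlier)
  expect_equal(res$outlier_index, 118L)
  clean <- grubbs_test(c(1, 2, 3), 0.05)
  expect_equal(clean$g_statistic, 1)
  expect_false(clean$is_outlier)
  expect_error(grubbs_test(rep(2, 10)), "degenerate")
})

test_that("species totals reproduce percentage arithmetic", {
  rec <- data.frame(
    species = c("deer", "cow", "horse", "wild_boar"),
    seeds_per_unit = c(16514, 108941, 20724, 903))
  st <- species_totals(rec)
  expect_equal(attr(st, "grand_total"), 147082)
  expect_equal(st$pct_of_site_total[match(c("deer", "cow", "horse", "wild_boar"),
                                          st$species)],
               c(11.2, 74.1, 14.1, 0.6))
  expect_lt(abs(sum(st$pct_of_site_total) - 100), 0.1)
  one <- species_totals(data.frame(species = "deer", seeds_per_unit = 7))
  expect_equal(one$pct_of_site_total, 100)
})

test_that("family summary computes abundance, frequency, unidentified share", {
  dep <- tiny_deposits()[1:2, ]
  seeds <- data.frame(
    deposit_id = c("d1", "d1", "d2"),
    family = c("famA", "famB", "famB"),
    genus = "", species_epithet = "",
    count = c(3L, 1L, 1L))
  fs <- family_summary(fecal_deposits(dep, seeds))
  expect_equal(fs$relative_abundance_pct[fs$family == "fama"], 60)
  expect_equal(fs$frequency_pct[fs$family == "fama"], 50)
  expect_equal(fs$relative_abundance_pct[fs$family == "famb"], 40)
  expect_equal(fs$frequency_pct[fs$family == "famb"], 100)
  expect_equal(sum(fs$relative_abundance_pct), 100, tolerance = 0.01)

  # frequencies invariant to scaling all counts
  seeds2 <- seeds; seeds2$count <- seeds2$count * 7L
  fs2 <- family_summary(fecal_deposits(dep, seeds2))
  expect_equal(fs2$frequency_pct, fs$frequency_pct)
  expect_equal(fs2$relative_abundance_pct, fs$relative_abundance_pct)

  # unidentified seeds counted in total but not the family pool
  seeds3 <- rbind(seeds, data.frame(deposit_id = "d2", family = "",
                                    genus = "", species_epithet = "",
                                    count = 5L))
  fs3 <- family_summary(fecal_deposits(dep, seeds3))
  expect_equal(attr(fs3, "unidentified_pct"), 100 * 5 / 10)
  expect_equal(sum(fs3$relative_abundance_pct), 100, tolerance = 0.01)
})

test_that("share_of_total and fecal_density use half-up rounding", {
  expect_equal(share_of_total(2614, 7074), 37)
  expect_equal(share_of_total(233, 7074, 1), 3.3)
  expect_equal(share_of_total(0, 7074), 0)
  expect_error(share_of_total(1, 0), "positive")
  expect_equal(fecal_density(118, 90), 1.3)
  expect_equal(fecal_density(0, 10), 0)
  expect_equal(fecal_density(90, 90), 1)
  expect_error(fecal_density(5, 0), "positive")
  expect_equal(round_half_up(0.125, 2), 0.13)  # base round() would give 0.12
})

test_that("microsite summary separates open and shrubby deposits", {
  dep <- tiny_deposits()
  dep$shrub_cover_pct <- c(0, 0, 40)
  dep <- rbind(dep, within(dep[1, ], { deposit_id <- "d4"; x_m <- 99 }))
  ms <- microsite_summary(fecal_deposits(dep, NULL))
  expect_equal(ms$pct_open, 75)
  expect_equal(ms$pct_shrubby, 25)
  expect_equal(ms$mean_cover_in_shrubby, 40)
  dep$shrub_cover_pct <- c(0, 20, 40, 0)
  ms2 <- microsite_summary(fecal_deposits(dep, NULL))
  expect_equal(ms2$mean_cover_in_shrubby, 30)
  dep$shrub_cover_pct <- 0
  ms3 <- microsite_summary(fecal_deposits(dep, NULL))
  expect_equal(ms3$pct_open, 100)
  expect_true(is.na(ms3$mean_cover_in_shrubby))
})
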