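# The hand-derived toys evaluate single rings centered on the pair
# distances (h = 0.5); the wider default bandwidth is exercised by the
# property tests below.
toy_grid <- function() structure(list(r = c(1, 5, 9), h = 0.5),
                                 class = "distance_grid")

test_that("box kernel is 1/(2h) on the closed band", {
  expect_equal(box_kernel(1.0, 1.0, 0.5), 1)
  expect_equal(box_kernel(1.6, 1.0, 0.5), 0)
  expect_equal(box_kernel(1.5, 1.0, 0.5), 1)  # boundary inclusive
  expect_equal(box_kernel(2, 5, 1.5), 0)
  expect_equal(box_kernel(4, 5, 1.5), 1 / 3)
})

test_that("ring_pairs returns ordered pairs in the closed band", {
  pat <- toy_pattern()
  expect_equal(ring_pairs(pat, 1, 0.5),
               cbind(i = c(1L, 2L), j = c(2L, 1L)))
  expect_equal(ring_pairs(pat, 9, 0.5),
               cbind(i = c(2L, 3L), j = c(3L, 2L)))
  expect_equal(nrow(ring_pairs(pat, 5, 0.5)), 0)
})

test_that("collinear toy reproduces hand-derived statistic values", {
  pat <- toy_pattern()
  km <- r_mark_correlation(pat, toy_grid())
  # ring r=1: ordered pairs (1,2),(2,1); c_t = (2+4)/2 = 3; mu = 4
  expect_equal(km$values[km$r == 1], 0.75)
  expect_equal(km$values[km$r == 9], 1.25)
  expect_true(km$missing[km$r == 5])
  expect_equal(km$mark_mean_mu, 4)

  imm <- schlather_imm(pat, toy_grid())
  expect_equal(imm$values[imm$r == 1], -0.375)
  expect_equal(imm$mark_variance_sigma2, 8 / 3)

  expect_equal(neighbor_counts(pat, 1.5), c(1L, 1L, 0L))
  expect_equal(neighbor_counts(pat, 1000), c(2L, 2L, 2L))
  expect_equal(neighbor_counts(pat, 0), c(0L, 0L, 0L))

  dc <- density_correlation(pat, distance_grid(r_max = 4, bin = 1, h = 0.5))
  expect_equal(dc$values[dc$r == 1.5], -sqrt(3) / 2, tolerance = 1e-12)
})

test_that("co-located twins drive Schlather correlation toward 1", {
  set.seed(11)
  x <- runif(25, 0, 50); y <- runif(25, 0, 50)
  m <- rgamma(25, 2, 0.1)
  pat <- marked_pattern(c(x, x), c(y, y), c(m, m),
                        study_window(0, 50, 0, 50))
  # the r=0.5, h=0.5 ring (band [0, 1]) holds exactly the twin pairs (d = 0),
  # whose marks are perfectly correlated
  imm0 <- schlather_imm(pat, distance_grid(r_max = 1, bin = 1, h = 0.5))
  expect_gt(imm0$values[1], 0.95)
})

test_that("statistics match the naive double-loop oracle", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    pat <- random_pattern(n)
    r <- runif(1, 1, 20); h <- runif(1, 0.5, 3)
    g <- structure(list(r = r, h = h), class = "distance_grid")
    expect_equal(r_mark_correlation(pat, g)$values, naive_rmark(pat, r, h),
                 tolerance = 1e-12)
    expect_equal(schlather_imm(pat, g)$values, naive_schlather(pat, r, h),
                 tolerance = 1e-12)
    expect_equal(neighbor_counts(pat, r), naive_neighbor_counts(pat, r))
    expect_equal(density_correlation(pat, g)$values,
                 naive_density_corr(pat, r), tolerance = 1e-12)
  }
})

test_that("mark-transform invariances hold", {
  set.seed(77)
  pat <- random_pattern(40)
  g <- distance_grid(r_max = 20, bin = 2, h = 2)
  km <- r_mark_correlation(pat, g)
  imm <- schlather_imm(pat, g)
  dc <- density_correlation(pat, g)

  scaled <- marked_pattern(pat$x, pat$y, pat$marks * 3.7, pat$window)
  expect_equal(r_mark_correlation(scaled, g)$values, km$values,
               tolerance = 1e-12)
  affine <- marked_pattern(pat$x, pat$y, 2.5 * pat$marks + 11, pat$window)
  expect_equal(schlather_imm(affine, g)$values, imm$values, tolerance = 1e-12)
  expect_equal(density_correlation(affine, g)$values, dc$values,
               tolerance = 1e-12)
  # Cauchy-Schwarz bound on the density correlation
  expect_true(all(abs(dc$values[!dc$missing]) <= 1 + 1e-12))
})

test_that("constant marks give k_m = 1; degenerate inputs error", {
  set.seed(5)
  pat <- random_pattern(20, mark_fun = function(n) rep(4.2, n))
  km <- r_mark_correlation(pat, distance_grid(r_max = 20, bin = 2, h = 2))
  expect_true(all(km$values[!km$missing] == 1))
  expect_error(schlather_imm(pat), "variance")
  expect_error(density_correlation(pat), "constant")
  zero <- random_pattern(10, mark_fun = function(n) rep(0, n))
  expect_error(r_mark_correlation(zero), "zero")
})

test_that("permutation-null means sit at their expectations", {
  set.seed(303)
  pat <- random_pattern(35)
  g <- distance_grid(r_max = 15, bin = 3, h = 2)
  n_perm <- 400
  km_sum <- 0; imm_sum <- 0
  for (s in 1:n_perm) {
    p2 <- marked_pattern(pat$x, pat$y, sample(pat$marks), pat$window)
    km_sum <- km_sum + r_mark_correlation(p2, g)$values
    imm_sum <- imm_sum + schlather_imm(p2, g)$values
  }
  # k_m averages to 1; I_mm to ~0 (O(1/n) bias allowed, 3 MC se tolerance)
  expect_true(all(abs(km_sum / n_perm - 1) < 0.1))
  expect_true(all(abs(imm_sum / n_perm) < 0.1))
})
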