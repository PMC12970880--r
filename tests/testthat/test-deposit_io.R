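test_that("deposits round-trip through CSV and validate", {
  x <- fecal_deposits(tiny_deposits(), tiny_seeds())
  dp <- withr::local_tempfile(fileext = ".csv")
  sp <- withr::local_tempfile(fileext = ".csv")
  write_deposits(x, dp, sp)
  y <- read_deposits(dp, sp)
  expect_identical(y$deposits$deposit_id, x$deposits$deposit_id)
  expect_identical(y$deposits$species, x$deposits$species)
  expect_identical(y$seeds$count, x$seeds$count)
  expect_equal(y$deposits$x_m, x$deposits$x_m, tolerance = 1e-9)
  expect_equal(y$deposits$sample_dw_g, x$deposits$sample_dw_g, tolerance = 1e-9)
})

test_that("schema violations are reported with row context", {
  bad <- tiny_deposits()
  bad$species[2] <- "sheep"
  expect_error(fecal_deposits(bad, NULL), "sheep.*row 2")
  orphan <- tiny_seeds()
  orphan$deposit_id[1] <- "nope"
  expect_error(fecal_deposits(tiny_deposits(), orphan), "unknown deposit_id")
  neg <- tiny_seeds()
  neg$count[2] <- -1L
  expect_error(fecal_deposits(tiny_deposits(), neg), "non-negative")
  oob <- tiny_deposits()
  oob$shrub_cover_pct[1] <- 130
  expect_error(fecal_deposits(oob, NULL), "shrub_cover_pct")
})

test_that("empty seeds table yields zero-count records for every deposit", {
  n <- 231
  dep <- data.frame(deposit_id = sprintf("s%03d", 1:n), site = "a",
                    date = "2020-05-01", species = "deer",
                    x_m = seq_len(n), y_m = 0, shrub_cover_pct = 0,
                    sample_dw_g = 2.5)
  dp <- withr::local_tempfile(fileext = ".csv")
  sp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dep, dp, row.names = FALSE)
  utils::write.csv(data.frame(deposit_id = character(), family = character(),
                              genus = character(), species_epithet = character(),
                              count = integer()), sp, row.names = FALSE)
  x <- read_deposits(dp, sp)
  expect_equal(nrow(x$deposits), n)
  expect_equal(unname(total_seed_counts(x)), rep(0L, n))
})

test_that("project_lonlat is a local tangent-plane projection", {
  ref <- c(-6.44, 37.12)
  expect_equal(unname(project_lonlat(rbind(ref), ref)), cbind(0, 0))
  # 1e-3 degrees of latitude = R * pi/180 * 1e-3 m
  p <- project_lonlat(rbind(ref + c(0, 1e-3)), ref)
  expect_equal(unname(p[1, "y"]), 111.1949, tolerance = 1e-6)
  expect_equal(unname(p[1, "x"]), 0)
  # symmetry: points mirrored about the reference negate exactly
  d <- c(2e-3, -3e-3)
  expect_equal(unname(project_lonlat(rbind(ref + d), ref)),
               -unname(project_lonlat(rbind(ref - d), ref)))
  # linearity in the offsets
  p1 <- project_lonlat(rbind(ref + c(1e-3, 2e-3)), ref)
  p2 <- project_lonlat(rbind(ref + c(2e-3, 4e-3)), ref)
  expect_equal(unname(p2), 2 * unname(p1))
  # projected distances track great-circle distances within 0.1% nearby
  rad <- pi / 180; R <- 6371000
  a <- ref + c(0.004, 0.006); b <- ref + c(-0.003, -0.002)
  pq <- project_lonlat(rbind(a, b), ref)
  gc <- 2 * R * asin(sqrt(
    sin((b[2] - a[2]) * rad / 2)^2 +
      cos(a[2] * rad) * cos(b[2] * rad) * sin((b[1] - a[1]) * rad / 2)^2))
  expect_equal(sqrt(sum((pq[1, ] - pq[2, ])^2)), gc, tolerance = 1e-3)
  expect_error(project_lonlat(rbind(ref + c(1.5, 0)), ref), "projected CRS")
})

test_that("to_marked_pattern delegates marks to the seed-load scaling", {
  x <- fecal_deposits(tiny_deposits(), tiny_seeds())
  pat <- to_marked_pattern(x)
  rec <- seed_content_records(x)
  expect_equal(pat$marks, rec$seeds_per_unit)
  # family marks: d1 has 3 Cyperaceae in 2.5 g (deer), d2 has 5 in 2.5 g (cow)
  cyp <- to_marked_pattern(x, "family", family = "Cyperaceae")
  expect_equal(cyp$marks, c(3 / 2.5 * 49.6, 5 / 2.5 * 630, 0))
  # absent family: all-zero marks, pattern still valid
  ghost <- to_marked_pattern(x, "family", family = "Poaceae")
  expect_equal(ghost$marks, c(0, 0, 0))
  expect_s3_class(ghost, "marked_pattern")
})

test_that("total marks are additive over family marks", {
  set.seed(42)
  d <- sim_site("martinazo_like", rng_seed = 3)
  total <- to_marked_pattern(d)$marks
  fams <- colnames(seed_count_matrix(d))
  by_fam <- sapply(fams, function(f)
    to_marked_pattern(d, "family", family = f)$marks)
  expect_equal(rowSums(by_fam), total, tolerance = 1e-12)
})

test_that("deposits lacking dry weight are excluded with a count", {
  dep <- tiny_deposits()
  dep <- rbind(dep, within(dep[1, ], { deposit_id <- "d4"; x_m <- 5 }),
               within(dep[1, ], { deposit_id <- "d5"; x_m <- 7 }))
  dep$sample_dw_g[4] <- NA
  x <- fecal_deposits(dep, tiny_seeds())
  expect_warning(pat <- to_marked_pattern(x), "excluding 1 deposit")
  expect_equal(pat$n, 4)
  expect_equal(attr(pat, "excluded"), 1)
})

test_that("patterns outside an explicit window are rejected", {
  w <- study_window(0, 5, 0, 5)
  expect_error(marked_pattern(c(1, 9), c(1, 1), c(1, 1), w), "outside")
  expect_error(study_window(3, 3, 0, 1), "exceed")
  expect_equal(study_window(0, 1000, 0, 900)$area_ha, 90)
})
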