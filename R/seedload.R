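#' Mean dung dry weight per defecation, by ungulate species
#'
#' Species-level mean dry weight of one defecation event, in grams. Defaults
#' are literature-derived means for the four ungulates handled by the
#' package: deer 49.6 g, cow 630 g, horse 300 g, wild boar 12.9 g. These
#' scale standardized seed content (seeds per gram) up to seeds per fecal
#' unit.
#'
#' @param deer,cow,horse,wild_boar mean dry weight per defecation (g).
#' @return named numeric vector of class `dung_weight_table`.
#' @export
dung_weight_table <- function(deer = 49.6, cow = 630, horse = 300,
                              wild_boar = 12.9) {
  w <- c(deer = deer, cow = cow, horse = horse, wild_boar = wild_boar)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("dung weights must be positive and finite")
  structure(w, class = "dung_weight_table")
}

#' Standardize seed content per gram of dry weight
#'
#' @param total_seed_count non-negative seed count(s).
#' @param sample_dw_g sample dry weight(s) in grams, > 0.
#' @return seeds per gram DW.
#' @examples
#' standardize_seed_content(30, 2.5)  # 12
#' @export
standardize_seed_content <- function(total_seed_count, sample_dw_g) {
  if (any(is.na(sample_dw_g)) || any(sample_dw_g <= 0))
    stop("sample dry weight must be positive")
  if (any(total_seed_count < 0)) stop("seed counts must be non-negative")
  total_seed_count / sample_dw_g
}

#' Scale standardized seed content to a whole fecal unit
#'
#' Seeds per deposition = seeds per gram DW times the species' mean dung dry
#' weight per defecation.
#'
#' @param seeds_per_g seeds per gram DW (vectorized).
#' @param species ungulate species label(s).
#' @param dung a [dung_weight_table()].
#' @return seeds per fecal unit.
#' @examples
#' per_fecal_unit(5, "cow")  # 3150
#' @export
per_fecal_unit <- function(seeds_per_g, species, dung = dung_weight_table()) {
  unknown <- setdiff(unique(species), names(dung))
  if (length(unknown))
    stop("species without a dung-weight entry: ", paste(unknown, collapse = ", "))
  unname(seeds_per_g * dung[species])
}

#' Critical value of the two-sided single-outlier Grubbs test
#'
#' `G_crit = ((n-1)/sqrt(n)) * sqrt(t^2 / (n - 2 + t^2))` where `t` is the
#' upper `alpha/(2n)` quantile of Student's t with `n - 2` degrees of
#' freedom.
#'
#' @param n sample size (>= 3).
#' @param alpha significance level in (0, 1).
#' @return the critical G value.
#' @examples
#' grubbs_critical(118, 0.05)  # ~3.44
#' @export
grubbs_critical <- function(n, alpha = 0.05) {
  if (n < 3) stop("Grubbs test requires n >= 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  t <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  (n - 1) / sqrt(n) * sqrt(t^2 / (n - 2 + t^2))
}

#' Two-sided single-outlier Grubbs test
#'
#' `G = max_i |x_i - mean| / sd` with the sample (n-1 denominator) standard
#' deviation, compared against [grubbs_critical()]. Applied once, no
#' iterative removal.
#'
#' @param values numeric vector, length >= 3, non-constant.
#' @param alpha significance level.
#' @return list of class `grubbs_result`: `g_statistic`, `g_critical`,
#'   `alpha`, `n`, `outlier_index`, `is_outlier`.
#' @export
grubbs_test <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3) stop("Grubbs test requires n >= 3")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate sample: zero variance")
  dev <- abs(values - mean(values))
  idx <- which.max(dev)
  g <- dev[idx] / s
  crit <- grubbs_critical(n, alpha)
  structure(list(g_statistic = g, g_critical = crit, alpha = alpha, n = n,
                 outlier_index = if (g > crit) idx else NA_integer_,
                 is_outlier = g > crit),
            class = "grubbs_result")
}

#' @export
print.grubbs_result <- function(x, ...) {
  cat(sprintf("Grubbs test: G = %.3f, critical G (alpha = %g, n = %d) = %.3f -> %s\n",
              x$g_statistic, x$alpha, x$n, x$g_critical,
              if (x$is_outlier) sprintf("outlier at index %d", x$outlier_index)
              else "no outlier"))
  invisible(x)
}

#' Round half away from zero
#'
#' Reported percentages use conventional half-up rounding (base `round()`
#' rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage share of a count
#'
#' @param part,total non-negative counts, `part <= total`, `total > 0`.
#' @param digits decimal places of the reported percentage.
#' @return `100 * part / total`, rounded half-up.
#' @examples
#' share_of_total(2614, 7074)       # 37
#' share_of_total(233, 7074, 1)     # 3.3
#' @export
share_of_total <- function(part, total, digits = 0) {
  if (total <= 0) stop("total must be positive")
  if (any(part < 0) || any(part > total)) stop("part must lie in [0, total]")
  round_half_up(100 * part / total, digits)
}

#' Fecal density
#'
#' @param n_units number of fecal units.
#' @param area_ha plot area in hectares, > 0.
#' @param digits decimal places (default 1).
#' @return feces per hectare.
#' @examples
#' fecal_density(118, 90)  # 1.3
#' @export
fecal_density <- function(n_units, area_ha, digits = 1) {
  if (area_ha <= 0) stop("area must be positive")
  round_half_up(n_units / area_ha, digits)
}

#' Per-deposit seed-content records
#'
#' One record per deposit that has a sample dry weight: standardized seed
#' content (seeds per gram DW) and the per-fecal-unit estimate (seeds per
#' deposition).
#'
#' @param x a `fecal_deposits` object.
#' @param dung a [dung_weight_table()].
#' @return data frame with columns `deposit_id`, `species`, `seeds_per_g`,
#'   `seeds_per_unit`.
#' @export
seed_content_records <- function(x, dung = dung_weight_table()) {
  stopifnot(inherits(x, "fecal_deposits"))
  dep <- x$deposits
  keep <- !is.na(dep$sample_dw_g)
  dep <- dep[keep, , drop = FALSE]
  cnt <- total_seed_counts(x)[keep]
  spg <- standardize_seed_content(cnt, dep$sample_dw_g)
  data.frame(deposit_id = dep$deposit_id, species = dep$species,
             seeds_per_g = unname(spg),
             seeds_per_unit = per_fecal_unit(spg, dep$species, dung),
             stringsAsFactors = FALSE)
}

#' Cumulated dispersed seeds per ungulate species
#'
#' Sums per-fecal-unit seed estimates over all deposits of each species and
#' expresses each species' contribution as a percentage of the site total
#' (reported to one decimal, half-up).
#'
#' @param records data frame as returned by [seed_content_records()], needing
#'   columns `species` and `seeds_per_unit`.
#' @return data frame with columns `species`, `cumulated_seeds`,
#'   `pct_of_site_total`, plus a `grand_total` attribute.
#' @export
species_totals <- function(records) {
  if (nrow(records) == 0) stop("no records")
  tot <- tapply(records$seeds_per_unit, records$species, sum)
  tot <- tot[order(-tot)]
  grand <- sum(tot)
  out <- data.frame(species = names(tot),
                    cumulated_seeds = unname(tot),
                    pct_of_site_total = round_half_up(100 * unname(tot) / grand, 1),
                    stringsAsFactors = FALSE)
  attr(out, "grand_total") <- grand
  out
}

#' Relative abundance and frequency of occurrence per plant family
#'
#' Abundance is each family's share of the pooled identified seed count;
#' frequency is the percentage of deposits in which the family occurs.
#' Unidentified seeds are excluded from the family pool and reported
#' separately via the `unidentified_pct` attribute (their share of all
#' recovered seeds).
#'
#' @param x a `fecal_deposits` object.
#' @return data frame with columns `family`, `relative_abundance_pct`,
#'   `frequency_pct`, sorted by decreasing frequency; attributes
#'   `unidentified_pct` and `n_deposits`.
#' @export
family_summary <- function(x) {
  stopifnot(inherits(x, "fecal_deposits"))
  m <- seed_count_matrix(x)
  if (ncol(m) == 0 || sum(m) == 0) stop("no seeds recorded")
  n_dep <- nrow(m)
  unid <- UNIDENTIFIED_KEY %in% colnames(m)
  total_all <- sum(m)
  unid_count <- if (unid) sum(m[, UNIDENTIFIED_KEY]) else 0L
  fam <- m[, setdiff(colnames(m), UNIDENTIFIED_KEY), drop = FALSE]
  if (ncol(fam) == 0 || sum(fam) == 0) stop("no identified seeds")
  out <- data.frame(
    family = colnames(fam),
    relative_abundance_pct = 100 * colSums(fam) / sum(fam),
    frequency_pct = 100 * colMeans(fam > 0),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$frequency_pct, -out$relative_abundance_pct, out$family), ]
  rownames(out) <- NULL
  attr(out, "unidentified_pct") <- 100 * unid_count / total_all
  attr(out, "n_deposits") <- n_dep
  out
}

#' Microsite physiognomy summary
#'
#' Classifies deposition microsites as open (shrub cover exactly 0) versus
#' shrubby, and averages shrub cover over shrubby microsites only.
#'
#' @param x a `fecal_deposits` object with `shrub_cover_pct` present for all
#'   deposits.
#' @param shrub_labels optional named character vector mapping `deposit_id`
#'   to the dominant shrub species of its microsite; when given, shares of
#'   each dominant shrub among shrubby microsites are reported.
#' @return list with `pct_open`, `pct_shrubby`, `mean_cover_in_shrubby`
#'   (`NA` when no shrubby microsite exists) and, when labels are supplied,
#'   `dominant_shrub_pct`.
#' @export
microsite_summary <- function(x, shrub_labels = NULL) {
  stopifnot(inherits(x, "fecal_deposits"))
  sc <- x$deposits$shrub_cover_pct
  if (any(is.na(sc))) stop("shrub_cover_pct must be present for all deposits")
  shrubby <- sc > 0
  out <- list(
    pct_open = 100 * mean(!shrubby),
    pct_shrubby = 100 * mean(shrubby),
    mean_cover_in_shrubby = if (any(shrubby)) mean(sc[shrubby]) else NA_real_)
  if (!is.null(shrub_labels) && any(shrubby)) {
    lab <- shrub_labels[x$deposits$deposit_id[shrubby]]
    lab <- lab[!is.na(lab)]
    if (length(lab))
      out$dominant_shrub_pct <- 100 * table(lab) / length(lab)
  }
  out
}
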