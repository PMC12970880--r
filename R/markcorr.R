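#' Distance grid for ring-based mark statistics
#'
#' Distance classes are rings centered at `r_centers` with a box-kernel
#' half-width `h`; the default lattice is centers at 0.5, 1.5, ..., 49.5 m.
#' The default half-width is 2.5 m, wider than the 0.5 m lattice spacing, so
#' successive rings overlap: at the fecal-deposit intensities this package
#' targets (1--12 points per hectare), non-overlapping 1 m rings hold only a
#' handful of point pairs and the ring estimators become so noisy that the
#' goodness-of-fit null distribution is dominated by sparse-ring spikes. The
#' bandwidth must be large enough to give an adequate number of pairs per
#' distance class while still resolving the biology of interest; pass
#' `h = 0.5` for strictly disjoint 1 m rings.
#'
#' @param r_max maximum distance (m).
#' @param bin lattice spacing of ring centers (m).
#' @param h box-kernel half-width (m).
#' @return object of class `distance_grid` with fields `r` and `h`.
#' @export
distance_grid <- function(r_max = 50, bin = 1, h = 2.5) {
  stopifnot(r_max > 0, bin > 0, h > 0)
  r <- seq(bin / 2, r_max - bin / 2, by = bin)
  if (!length(r) || any(r <= 0)) stop("invalid distance grid")
  structure(list(r = r, h = h), class = "distance_grid")
}

#' Box kernel
#'
#' Uniform kernel of half-width `h`: `1/(2h)` when `|d - r| <= h`
#' (boundary inclusive), else 0.
#'
#' @param d distance(s) (m).
#' @param r ring center (m).
#' @param h half-width (m), > 0.
#' @return kernel value(s).
#' @export
box_kernel <- function(d, r, h) {
  stopifnot(h > 0)
  ifelse(abs(d - r) <= h, 1 / (2 * h), 0)
}

## Full Euclidean distance matrix; O(n^2) is fine at the sample sizes used
## (a few hundred deposits per site).
pair_distance_matrix <- function(pattern) {
  as.matrix(stats::dist(cbind(pattern$x, pattern$y)))
}

#' Ordered point pairs within a distance ring
#'
#' All ordered pairs (i, j), i != j, whose inter-point distance lies in the
#' closed band `[r - h, r + h]`. Both (i, j) and (j, i) are returned, so the
#' pair count per ring is always even.
#'
#' @param pattern a [marked_pattern()].
#' @param r ring center (m).
#' @param h half-width (m).
#' @return two-column integer matrix of (i, j) indices (possibly 0 rows).
#' @export
ring_pairs <- function(pattern, r, h) {
  stopifnot(inherits(pattern, "marked_pattern"))
  d <- pair_distance_matrix(pattern)
  sel <- which(abs(d - r) <= h & row(d) != col(d), arr.ind = TRUE)
  m <- cbind(i = unname(sel[, 1]), j = unname(sel[, 2]))
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

## Precomputed ring structure: per bin, index vectors ii/jj of the ordered
## pairs in that ring. Point locations are fixed under random labelling, so
## this is built once per pattern and reused across all mark permutations.
ring_index <- function(pattern, grid) {
  d <- pair_distance_matrix(pattern)
  off <- row(d) != col(d)
  lapply(grid$r, function(r) {
    sel <- which(abs(d - r) <= grid$h & off, arr.ind = TRUE)
    list(ii = sel[, 1], jj = sel[, 2], count = nrow(sel))
  })
}

## Neighbor-count matrix: K[i, b] = number of other points within grid$r[b]
## of point i (cumulative disc, ties at d == r included).
neighbor_count_matrix <- function(pattern, r_vec) {
  d <- pair_distance_matrix(pattern)
  sapply(r_vec, function(r) rowSums(d <= r) - 1L)
}

## Fast statistic evaluators on a precomputed ring structure. These are the
## single code path used for both observed and simulated curves; tests check
## them against naive double loops.
eval_rmark <- function(marks, ri, mu) {
  vapply(ri, function(b) {
    if (b$count == 0) return(NA_real_)
    mean(marks[b$ii]) / mu
  }, numeric(1))
}

eval_schlather <- function(marks, ri, sigma2) {
  vapply(ri, function(b) {
    if (b$count == 0) return(NA_real_)
    mi <- marks[b$ii]; mj <- marks[b$jj]
    mur <- mean(mi)               # == mean(mj): ordered pairs are symmetric
    mean((mi - mur) * (mj - mur)) / sigma2
  }, numeric(1))
}

eval_density <- function(marks, K) {
  apply(K, 2, function(k) {
    if (stats::sd(k) == 0) return(NA_real_)
    stats::cor(marks, k)
  })
}

make_curve <- function(statistic, grid, values, pair_counts, pattern) {
  mu <- mean(pattern$marks)
  sigma2 <- mean((pattern$marks - mu)^2)   # population variance
  structure(
    list(statistic = statistic, r = grid$r, h = grid$h,
         values = values, pair_counts = pair_counts,
         missing = is.na(values),
         mark_mean_mu = mu, mark_variance_sigma2 = sigma2,
         intensity_lambda = pattern$n /
           ((pattern$window$x_max - pattern$window$x_min) *
              (pattern$window$y_max - pattern$window$y_min))),
    class = "markcorr_curve")
}

#' @export
print.markcorr_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d bins (h = %g m), %d empty; mu = %.3g, sigma2 = %.3g\n",
              x$statistic, length(x$r), x$h, sum(x$missing),
              x$mark_mean_mu, x$mark_variance_sigma2))
  invisible(x)
}

#' @export
as.data.frame.markcorr_curve <- function(x, ...) {
  data.frame(statistic = x$statistic, r_center = x$r, value = x$values,
             pair_count = x$pair_counts, missing_flag = x$missing)
}

#' r-mark correlation function
#'
#' For each distance ring, the mean mark of the first point of all ordered
#' pairs in the ring, normalized by the mean mark over all points:
#' `k_m(r) = c_t(r) / mu`. `k_m(r) > 1` means points with a neighbor at
#' distance r carry above-average marks (a positive effect of aggregation);
#' `k_m(r) < 1` a negative one. Rings with no pairs are flagged missing.
#'
#' @param pattern a [marked_pattern()] with mark mean > 0.
#' @param grid a [distance_grid()].
#' @return a `markcorr_curve`.
#' @export
r_mark_correlation <- function(pattern, grid = distance_grid()) {
  stopifnot(inherits(pattern, "marked_pattern"))
  mu <- mean(pattern$marks)
  if (mu == 0) stop("normalization undefined: all marks are zero")
  ri <- ring_index(pattern, grid)
  make_curve("r_mark", grid, eval_rmark(pattern$marks, ri, mu),
             vapply(ri, `[[`, integer(1), "count"), pattern)
}

#' Schlather's mark correlation I_mm(r)
#'
#' Moran-like spatial mark correlation: for each ring, the mean over ordered
#' pairs of `(m_i - mu(r)) (m_j - mu(r))`, with `mu(r)` the mean mark over
#' the pairs in that ring, normalized by the population mark variance
#' `sigma^2` (denominator n). Values near 0 indicate no spatial covariance
#' in marks at distance r; positive values indicate nearby points carry
#' similar marks.
#'
#' @param pattern a [marked_pattern()] with non-constant marks.
#' @param grid a [distance_grid()].
#' @return a `markcorr_curve`.
#' @export
schlather_imm <- function(pattern, grid = distance_grid()) {
  stopifnot(inherits(pattern, "marked_pattern"))
  mu <- mean(pattern$marks)
  sigma2 <- mean((pattern$marks - mu)^2)
  if (sigma2 == 0) stop("mark variance is zero")
  ri <- ring_index(pattern, grid)
  make_curve("schlather", grid, eval_schlather(pattern$marks, ri, sigma2),
             vapply(ri, `[[`, integer(1), "count"), pattern)
}

#' Neighbor counts within distance r
#'
#' `K_i = #\{j != i : ||x_i - x_j|| <= r\}`, a cumulative disc count (ties
#' at exactly d = r included).
#'
#' @param pattern a [marked_pattern()].
#' @param r disc radius (m).
#' @return integer vector of counts, one per point.
#' @export
neighbor_counts <- function(pattern, r) {
  stopifnot(inherits(pattern, "marked_pattern"), length(r) == 1)
  d <- pair_distance_matrix(pattern)
  as.integer(rowSums(d <= r) - 1L)
}

#' Mark-density correlation function C_m,K(r)
#'
#' Pearson correlation, over all points, between the mark `m_i` and the
#' neighbor count `K_i(r)` within distance r. The overall intensity cancels
#' in the correlation. Bins where all `K_i(r)` are equal are flagged
#' missing.
#'
#' @param pattern a [marked_pattern()] with at least 3 points and
#'   non-constant marks.
#' @param grid a [distance_grid()].
#' @return a `markcorr_curve`; `pair_counts` here hold the total neighbor
#'   count per disc radius.
#' @export
density_correlation <- function(pattern, grid = distance_grid()) {
  stopifnot(inherits(pattern, "marked_pattern"))
  if (pattern$n < 3) stop("density correlation requires at least 3 points")
  if (stats::sd(pattern$marks) == 0) stop("marks are constant")
  K <- neighbor_count_matrix(pattern, grid$r)
  make_curve("density_corr", grid, eval_density(pattern$marks, K),
             as.integer(colSums(K)), pattern)
}

#' Compute a mark-correlation statistic by name
#'
#' @param pattern a [marked_pattern()].
#' @param statistic one of `"r_mark"`, `"schlather"`, `"density_corr"`.
#' @param grid a [distance_grid()].
#' @return a `markcorr_curve`.
#' @export
mark_statistic <- function(pattern,
                           statistic = c("r_mark", "schlather", "density_corr"),
                           grid = distance_grid()) {
  statistic <- match.arg(statistic)
  switch(statistic,
         r_mark = r_mark_correlation(pattern, grid),
         schlather = schlather_imm(pattern, grid),
         density_corr = density_correlation(pattern, grid))
}
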