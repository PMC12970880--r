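#' Random-labelling simulations of a marked pattern
#'
#' The null model throughout the package: point locations are held fixed and
#' marks are permuted uniformly at random among points (the mark multiset is
#' conserved exactly).
#'
#' @param pattern a [marked_pattern()].
#' @param n_sim number of simulations (>= 1).
#' @param rng_seed integer seed; identical seeds give identical ensembles.
#' @return list of `n_sim` marked patterns sharing `pattern`'s points.
#' @export
random_labelling <- function(pattern, n_sim = 199, rng_seed = 1) {
  stopifnot(inherits(pattern, "marked_pattern"), n_sim >= 1)
  set.seed(rng_seed)
  lapply(seq_len(n_sim), function(s)
    marked_pattern(pattern$x, pattern$y, sample(pattern$marks),
                   window = pattern$window))
}

## Internal engine: evaluate one statistic on the observed marks and on
## n_sim mark permutations, reusing the ring / neighbor-count geometry
## (locations never change under random labelling).
simulate_null_curves <- function(pattern, statistic, grid, n_sim, rng_seed) {
  marks <- pattern$marks
  mu <- mean(marks)
  sigma2 <- mean((marks - mu)^2)
  if (statistic == "r_mark" && mu == 0)
    stop("normalization undefined: all marks are zero")
  if (statistic %in% c("schlather", "density_corr") && sigma2 == 0)
    stop("mark variance is zero")

  if (statistic == "density_corr") {
    K <- neighbor_count_matrix(pattern, grid$r)
    evalf <- function(m) eval_density(m, K)
    counts <- as.integer(colSums(K))
  } else {
    ri <- ring_index(pattern, grid)
    counts <- vapply(ri, `[[`, integer(1), "count")
    evalf <- switch(statistic,
                    r_mark = function(m) eval_rmark(m, ri, mu),
                    schlather = function(m) eval_schlather(m, ri, sigma2))
  }
  observed <- make_curve(statistic, grid, evalf(marks), counts, pattern)
  set.seed(rng_seed)
  sims <- matrix(NA_real_, nrow = n_sim, ncol = length(grid$r))
  for (s in seq_len(n_sim)) sims[s, ] <- evalf(sample(marks))
  list(observed = observed, sims = sims)
}

#' Random-labelling null ensemble for a mark statistic
#'
#' @param pattern a [marked_pattern()].
#' @param statistic `"r_mark"`, `"schlather"` or `"density_corr"`.
#' @param grid a [distance_grid()].
#' @param n_sim number of random-labelling simulations (default 199).
#' @param rng_seed integer seed.
#' @return object of class `null_ensemble`: the observed `markcorr_curve`
#'   plus an `n_sim x n_bins` matrix of simulated curves.
#' @export
null_ensemble <- function(pattern,
                          statistic = c("r_mark", "schlather", "density_corr"),
                          grid = distance_grid(), n_sim = 199, rng_seed = 1) {
  statistic <- match.arg(statistic)
  stopifnot(n_sim >= 1)
  res <- simulate_null_curves(pattern, statistic, grid, n_sim, rng_seed)
  structure(list(statistic = statistic, n_sim = n_sim, rng_seed = rng_seed,
                 r = grid$r, observed = res$observed, curves = res$sims),
            class = "null_ensemble")
}

#' Pointwise simulation envelopes
#'
#' Per distance bin, the k-th smallest and k-th largest simulated values.
#' With `k = 5` and 199 simulations the implied two-sided pointwise level is
#' `2k / (n_sim + 1) = 0.05`.
#'
#' @param ensemble a [null_ensemble()] or a numeric matrix of simulated
#'   curves (rows = simulations).
#' @param k envelope rank (default 5); requires `2k <= n_sim`.
#' @return list of class `envelope_result`: `lo`, `hi`, `k`, `level`.
#' @export
pointwise_envelopes <- function(ensemble, k = 5) {
  curves <- if (inherits(ensemble, "null_ensemble")) ensemble$curves else ensemble
  n_sim <- nrow(curves)
  if (k < 1 || 2 * k > n_sim)
    stop("envelope rank k must satisfy 1 <= 2k <= n_sim")
  kth <- function(v, k, high = FALSE) {
    v <- v[!is.na(v)]
    if (length(v) < n_sim) return(NA_real_)   # bin missing in some curve
    v <- sort(v)
    if (high) v[length(v) - k + 1] else v[k]
  }
  structure(list(lo = apply(curves, 2, kth, k = k),
                 hi = apply(curves, 2, kth, k = k, high = TRUE),
                 k = k, n_sim = n_sim, level = 2 * k / (n_sim + 1)),
            class = "envelope_result")
}

#' Rank-based goodness-of-fit test over a distance interval
#'
#' Summed-deviation statistic with leave-one-out null means: writing `H_i`
#' for curve i (observed = 0, simulations 1..n_sim), each curve gets
#' `u_i = sum_bins (H_i(r) - mean of the other curves at r)^2`, summed over
#' the bins in `[r_min, r_max]` that are valid in every curve. The p-value
#' is `(1 + #\{sims with u_i >= u_0\}) / (1 + n_sim)`; the smallest
#' attainable p with 199 simulations is 0.005.
#'
#' @param ensemble a [null_ensemble()].
#' @param r_min,r_max distance interval (defaults: the full grid).
#' @return list of class `gof_result`: `u_observed`, `u_simulated`,
#'   `p_value`, `r_min`, `r_max`, `n_bins_used`.
#' @export
gof_test <- function(ensemble, r_min = -Inf, r_max = Inf) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  H <- rbind(ensemble$observed$values, ensemble$curves)
  in_range <- ensemble$r >= r_min & ensemble$r <= r_max
  valid <- in_range & colSums(is.na(H)) == 0     # common support across curves
  if (!any(valid)) stop("no jointly valid bins in the requested r range")
  H <- H[, valid, drop = FALSE]
  n_curves <- nrow(H)
  tot <- colSums(H)
  loo <- (matrix(tot, n_curves, ncol(H), byrow = TRUE) - H) / (n_curves - 1)
  u <- rowSums((H - loo)^2)
  structure(list(u_observed = u[1], u_simulated = u[-1],
                 p_value = (1 + sum(u[-1] >= u[1])) / (1 + ensemble$n_sim),
                 r_min = r_min, r_max = r_max, n_bins_used = sum(valid)),
            class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat(sprintf("GoF test: u_obs = %.4g over %d bins, p = %.3f\n",
              x$u_observed, x$n_bins_used, x$p_value))
  invisible(x)
}

#' Full mark-correlation analysis with envelopes and GoF test
#'
#' Runs one statistic on one pattern: observed curve, 199 (by default)
#' random-labelling simulations, pointwise k-th-extreme envelopes, null mean
#' curve, and the rank-based goodness-of-fit test over `[r_min, r_max]`.
#' Deterministic given `rng_seed`.
#'
#' @param pattern a [marked_pattern()].
#' @param statistic `"r_mark"`, `"schlather"` or `"density_corr"`.
#' @param grid a [distance_grid()].
#' @param n_sim number of simulations.
#' @param k envelope rank.
#' @param rng_seed integer seed.
#' @param r_min,r_max GoF distance interval (default: full grid).
#' @return list of class `mark_analysis`: `statistic`, `curve` (observed),
#'   `null_mean`, `envelope`, `gof`, `table` (per-bin data frame with
#'   observed value, null mean, envelope bounds and an outside-envelope
#'   flag), and the configuration used.
#' @export
run_mark_analysis <- function(pattern,
                              statistic = c("r_mark", "schlather", "density_corr"),
                              grid = distance_grid(), n_sim = 199, k = 5,
                              rng_seed = 1, r_min = -Inf, r_max = Inf) {
  statistic <- match.arg(statistic)
  ens <- null_ensemble(pattern, statistic, grid, n_sim, rng_seed)
  env <- pointwise_envelopes(ens, k)
  gof <- gof_test(ens, r_min, r_max)
  null_mean <- colMeans(ens$curves)
  obs <- ens$observed$values
  tab <- data.frame(
    r_center = grid$r,
    observed = obs,
    null_mean = null_mean,
    lo = env$lo, hi = env$hi,
    pair_count = ens$observed$pair_counts,
    outside = !is.na(obs) & !is.na(env$lo) & (obs < env$lo | obs > env$hi))
  structure(list(statistic = statistic, curve = ens$observed,
                 null_mean = null_mean, envelope = env, gof = gof,
                 table = tab, n_sim = n_sim, k = k, rng_seed = rng_seed),
            class = "mark_analysis")
}

#' @export
print.mark_analysis <- function(x, ...) {
  cat(sprintf("mark analysis [%s]: n_sim = %d, k = %d, GoF p = %.3f\n",
              x$statistic, x$n_sim, x$k, x$gof$p_value))
  out <- x$table$r_center[x$table$outside]
  if (length(out))
    cat("  outside envelope at r =", paste(out, collapse = ", "), "m\n")
  invisible(x)
}
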