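# Naive double-loop oracles for the ring statistics. Deliberately slow and
# independent of the package's vectorized/ precomputed-index code path.

naive_rmark <- function(pat, r, h) {
  n <- pat$n
  num <- 0; den <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((pat$x[i] - pat$x[j])^2 + (pat$y[i] - pat$y[j])^2)
    k <- if (abs(d - r) <= h) 1 / (2 * h) else 0
    num <- num + pat$marks[i] * k
    den <- den + k
  }
  if (den == 0) return(NA_real_)
  (num / den) / mean(pat$marks)
}

naive_schlather <- function(pat, r, h) {
  n <- pat$n
  mi <- c(); mj <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((pat$x[i] - pat$x[j])^2 + (pat$y[i] - pat$y[j])^2)
    if (abs(d - r) <= h) { mi <- c(mi, pat$marks[i]); mj <- c(mj, pat$marks[j]) }
  }
  if (!length(mi)) return(NA_real_)
  mur <- mean(mi)
  sigma2 <- mean((pat$marks - mean(pat$marks))^2)
  mean((mi - mur) * (mj - mur)) / sigma2
}

naive_neighbor_counts <- function(pat, r) {
  n <- pat$n
  out <- integer(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- sqrt((pat$x[i] - pat$x[j])^2 + (pat$y[i] - pat$y[j])^2)
    if (d <= r) out[i] <- out[i] + 1L
  }
  out
}

naive_density_corr <- function(pat, r) {
  K <- naive_neighbor_counts(pat, r)
  if (length(unique(K)) == 1) return(NA_real_)
  stats::cor(pat$marks, K)
}

# Spec's collinear toy: points at 0, 1, 10 m on a line, marks 2, 4, 6.
toy_pattern <- function() {
  marked_pattern(x = c(0, 1, 10), y = c(0, 0, 0), marks = c(2, 4, 6),
                 window = study_window(-1, 11, -1, 1))
}

random_pattern <- function(n, mark_fun = function(n) rgamma(n, 2, 0.5),
                           side = 30) {
  marked_pattern(runif(n, 0, side), runif(n, 0, side), mark_fun(n),
                 window = study_window(0, side, 0, side))
}

# Minimal valid deposit table used across io tests.
tiny_deposits <- function() {
  data.frame(
    deposit_id = c("d1", "d2", "d3"),
    site = "toy",
    date = c("2020-04-01", "2020-04-02", "2020-04-03"),
    species = c("deer", "cow", "horse"),
    x_m = c(0, 10, 20), y_m = c(0, 5, 1),
    shrub_cover_pct = c(0, 40, 0),
    sample_dw_g = c(2.5, 2.5, 2.0),
    stringsAsFactors = FALSE)
}

tiny_seeds <- function() {
  data.frame(
    deposit_id = c("d1", "d1", "d2", "d3"),
    family = c("Cyperaceae", "Fabaceae", "cyperaceae ", "Plantaginaceae"),
    genus = c("Carex", "", "", ""),
    species_epithet = "",
    count = c(3L, 1L, 5L, 2L),
    stringsAsFactors = FALSE)
}
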