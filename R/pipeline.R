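#' Select plant families for spatial analysis
#'
#' The k families with the highest frequency of occurrence (percentage of
#' deposits in which the family is present). Ties are broken by higher
#' pooled abundance, then lexicographically. Unidentified seeds never
#' qualify.
#'
#' @param x a `fecal_deposits` object.
#' @param k number of families (default 3).
#' @return character vector of family names (length `<= k`; a warning is
#'   issued when fewer families exist than requested).
#' @export
select_families <- function(x, k = 3) {
  stopifnot(k >= 1)
  fs <- family_summary(x)    # already sorted by frequency, abundance, name
  if (nrow(fs) < k)
    warning(sprintf("only %d families available (requested %d)", nrow(fs), k))
  utils::head(fs$family, k)
}

#' Pipeline run configuration
#'
#' @param input list with `deposits` and `seeds` CSV paths, or `NULL` to
#'   simulate from `template`.
#' @param template a [site_template()] name or [scenario_config()] used when
#'   `input` is `NULL`.
#' @param dung a [dung_weight_table()] (overridable).
#' @param grid a [distance_grid()] (default: 1 m bins to 50 m, h = 0.5).
#' @param n_sim random-labelling simulations (default 199).
#' @param k envelope rank (default 5; requires `n_sim >= 2k`).
#' @param alpha_grubbs significance level of the outlier screen.
#' @param n_families how many top-frequency families get their own spatial
#'   analysis (default 3).
#' @param rng_seed master seed; per-analysis streams are derived from it by
#'   fixed offsets so adding an analysis never perturbs earlier ones.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `run_config`.
#' @export
run_config <- function(input = NULL, template = "martinazo_like",
                       dung = dung_weight_table(), grid = distance_grid(),
                       n_sim = 199, k = 5, alpha_grubbs = 0.05,
                       n_families = 3, rng_seed = 1, out_dir = NULL) {
  if (n_sim < 2 * k) stop("n_sim must be at least 2k")
  stopifnot(n_families >= 1)
  structure(list(input = input, template = template, dung = dung, grid = grid,
                 n_sim = n_sim, k = k, alpha_grubbs = alpha_grubbs,
                 n_families = n_families, rng_seed = rng_seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' Recognized top-level keys mirror the [run_config()] arguments; `dung` may
#' be a named object of per-species weights and `grid` an object with
#' `r_max`, `bin`, `h`.
#'
#' @param path JSON file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  if (!is.null(j$input)) args$input <- as.list(j$input)
  for (key in c("template", "n_sim", "k", "alpha_grubbs", "n_families",
                "rng_seed", "out_dir"))
    if (!is.null(j[[key]])) args[[key]] <- j[[key]]
  if (!is.null(j$dung)) args$dung <- do.call(dung_weight_table, as.list(j$dung))
  if (!is.null(j$grid)) args$grid <- do.call(distance_grid, as.list(j$grid))
  do.call(run_config, args)
}

write_analysis_outputs <- function(analysis, label, out_dir) {
  stem <- file.path(out_dir, paste0("markcorr_", label, "_", analysis$statistic))
  utils::write.csv(analysis$table, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(statistic = analysis$statistic, mark = label,
         n_sim = analysis$n_sim, k = analysis$k,
         rng_seed = analysis$rng_seed,
         r_min = analysis$gof$r_min, r_max = analysis$gof$r_max,
         u_observed = analysis$gof$u_observed,
         p_value = analysis$gof$p_value,
         envelope_level = analysis$envelope$level),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
}

#' Run the full seed-dispersal analysis pipeline
#'
#' Stages: (1) load the two-table dataset or simulate it from a template;
#' (2) Grubbs screen on per-sample raw total seed counts -- a flagged
#' sample is excluded from all seed-content analyses (but not from the
#' fecal-density count) and reported; (3) descriptive summaries (per-species
#' cumulated seeds, family abundance/frequency, microsites, fecal density);
#' (4) mark-correlation analyses of total per-unit seed content with all
#' three statistics; (5) the same for the top-frequency plant families
#' (zero marks retained: absence of a family in a deposit is information).
#' All outputs are written to `config$out_dir` when set, together with a run
#' manifest. Deterministic given `config$rng_seed`.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `data` (screened),
#'   `excluded` (Grubbs-flagged deposit ids), `grubbs`, `records`,
#'   `species_totals`, `family_summary`, `microsites`, `fecal_density`,
#'   `families`, `analyses` (nested: `$total` and one entry per family, each
#'   holding the three `mark_analysis` objects), `manifest`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_stage <- function(...) message(sprintf(...))

  ## stage 1: data
  if (!is.null(config$input)) {
    data <- read_deposits(config$input$deposits, config$input$seeds)
    log_stage("load: %d deposits, %d seed rows",
              nrow(data$deposits), nrow(data$seeds))
  } else {
    data <- sim_site(config$template, rng_seed = config$rng_seed)
    log_stage("simulate: %d deposits, %d seed rows",
              nrow(data$deposits), nrow(data$seeds))
  }
  n_all_deposits <- nrow(data$deposits)

  ## stage 2: outlier screen on raw per-sample total seed counts
  counts <- total_seed_counts(data)
  grubbs <- NULL
  excluded <- character(0)
  if (length(counts) >= 3 && stats::sd(counts) > 0) {
    grubbs <- grubbs_test(counts, alpha = config$alpha_grubbs)
    if (grubbs$is_outlier) {
      excluded <- names(counts)[grubbs$outlier_index]
      keep <- !data$deposits$deposit_id %in% excluded
      data <- fecal_deposits(data$deposits[keep, , drop = FALSE],
                             data$seeds[!data$seeds$deposit_id %in% excluded, ,
                                        drop = FALSE])
      log_stage("grubbs: excluded sample %s (G = %.2f > %.2f)",
                excluded, grubbs$g_statistic, grubbs$g_critical)
    } else {
      log_stage("grubbs: no outlier (G = %.2f <= %.2f)",
                grubbs$g_statistic, grubbs$g_critical)
    }
  }

  ## stage 3: descriptive summaries
  records <- seed_content_records(data, config$dung)
  sp_tot <- species_totals(records)
  fam_sum <- family_summary(data)
  micro <- microsite_summary(data)
  ## density uses every recorded deposit, including a Grubbs-flagged one
  dens <- fecal_density(n_all_deposits,
                        area_ha = attr(data, "window_area_ha") %||%
                          site_area_ha(data))
  log_stage("summaries: %d species, %d families, density %.1f feces/ha",
            nrow(sp_tot), nrow(fam_sum), dens)

  ## stages 4-5: mark-correlation analyses; fixed seed offsets per analysis
  families <- select_families(data, config$n_families)
  stats_run <- c("r_mark", "schlather", "density_corr")
  analyses <- list()
  offset <- 0L
  run_three <- function(pattern) {
    out <- list()
    for (s in stats_run) {
      offset <<- offset + 1L
      out[[s]] <- run_mark_analysis(pattern, s, grid = config$grid,
                                    n_sim = config$n_sim, k = config$k,
                                    rng_seed = (config$rng_seed + 1000L * offset) %%
                                      .Machine$integer.max)
    }
    out
  }
  pattern_total <- to_marked_pattern(data, "total", dung = config$dung)
  analyses$total <- run_three(pattern_total)
  log_stage("markcorr[total]: GoF p = %s",
            paste(sprintf("%s %.3f", stats_run,
                          vapply(analyses$total,
                                 function(a) a$gof$p_value, 0)),
                  collapse = ", "))
  for (fam in families) {
    pat <- to_marked_pattern(data, "family", family = fam, dung = config$dung)
    analyses[[fam]] <- run_three(pat)
    log_stage("markcorr[%s]: GoF p = %s", fam,
              paste(sprintf("%s %.3f", stats_run,
                            vapply(analyses[[fam]],
                                   function(a) a$gof$p_value, 0)),
                    collapse = ", "))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("grazemark")),
    rng_seed = config$rng_seed, n_sim = config$n_sim, k = config$k,
    alpha_grubbs = config$alpha_grubbs, n_families = config$n_families,
    grid = list(r = range(config$grid$r), h = config$grid$h),
    input = config$input,
    template = if (is.null(config$input) && is.character(config$template))
      config$template else NULL,
    n_deposits = n_all_deposits, excluded = as.list(excluded))

  result <- structure(
    list(data = data, excluded = excluded, grubbs = grubbs,
         records = records, species_totals = sp_tot,
         family_summary = fam_sum, microsites = micro,
         fecal_density = dens, families = families,
         analyses = analyses, manifest = manifest),
    class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sp_tot, file.path(config$out_dir, "species_totals.csv"),
                     row.names = FALSE)
    utils::write.csv(fam_sum, file.path(config$out_dir, "family_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(micro[!vapply(micro, is.null, TRUE)]),
                     file.path(config$out_dir, "microsites.csv"),
                     row.names = FALSE)
    if (!is.null(grubbs))
      jsonlite::write_json(
        list(g = grubbs$g_statistic, g_crit = grubbs$g_critical,
             alpha = grubbs$alpha, n = grubbs$n,
             outlier_id = if (length(excluded)) excluded else NULL),
        file.path(config$out_dir, "grubbs.json"),
        auto_unbox = TRUE, digits = NA)
    for (label in names(analyses))
      for (a in analyses[[label]])
        write_analysis_outputs(a, label, config$out_dir)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Plot area backing the density summary: bounding box of all recorded
## deposits (the window is never part of the input tables).
site_area_ha <- function(data) {
  dx <- diff(range(data$deposits$x_m))
  dy <- diff(range(data$deposits$y_m))
  if (dx <= 0 || dy <= 0) return(NA_real_)
  dx * dy / 1e4
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("pipeline result: %d deposits (%d excluded by Grubbs screen)\n",
              nrow(x$data$deposits), length(x$excluded)))
  cat("  families analysed:", paste(x$families, collapse = ", "), "\n")
  for (label in names(x$analyses)) {
    p <- vapply(x$analyses[[label]], function(a) a$gof$p_value, 0)
    cat(sprintf("  %s: %s\n", label,
                paste(sprintf("%s p=%.3f", names(p), p), collapse = ", ")))
  }
  invisible(x)
}
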