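#' @keywords internal
"_PACKAGE"

## Valid ungulate species labels used throughout the package.
UNGULATE_SPECIES <- c("deer", "cow", "horse", "wild_boar")

## Reserved taxon label for seeds that could not be identified to family.
UNIDENTIFIED_KEY <- "unidentified"

#' Normalize a taxon key
#'
#' Taxon keys (family names, and optionally genus / species epithet) compare
#' case-insensitively after whitespace trimming. Empty strings and the
#' reserved label `"unidentified"` both map to the unidentified pool.
#'
#' @param x character vector of taxon labels.
#' @return lower-case, trimmed character vector; empty labels become
#'   `"unidentified"`.
#' @export
normalize_taxon <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == ""] <- UNIDENTIFIED_KEY
  x
}

#' Rectangular study window
#'
#' The observation window of a marked point pattern, an axis-aligned
#' rectangle in planar meters. The plot area in hectares is derived from the
#' side lengths.
#'
#' @param x_min,x_max,y_min,y_max window limits in meters.
#' @return an object of class `study_window` with fields `x_min`, `x_max`,
#'   `y_min`, `y_max` and `area_ha`.
#' @examples
#' w <- study_window(0, 400, 0, 250)
#' w$area_ha  # 10 ha
#' @export
study_window <- function(x_min, x_max, y_min, y_max) {
  stopifnot(is.finite(x_min), is.finite(x_max), is.finite(y_min), is.finite(y_max))
  if (x_max <= x_min || y_max <= y_min)
    stop("study_window: x_max must exceed x_min and y_max must exceed y_min")
  structure(
    list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
         area_ha = (x_max - x_min) * (y_max - y_min) / 1e4),
    class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("study window [%g, %g] x [%g, %g] m (%.2f ha)\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$area_ha))
  invisible(x)
}

#' Fecal-deposit dataset
#'
#' Bundles a deposits table (one georeferenced fecal unit per row) with a
#' long-format seed-count table, validating both against the package schema.
#' This is the container returned by [read_deposits()] and [sim_site()].
#'
#' @param deposits data frame with columns `deposit_id`, `site`, `date`,
#'   `species` (one of deer, cow, horse, wild_boar), `x_m`, `y_m`,
#'   `shrub_cover_pct` (0--100) and `sample_dw_g` (grams, `NA` allowed; a
#'   deposit without dry weight is excluded from seed-content operations but
#'   retained for density counts).
#' @param seeds data frame with columns `deposit_id`, `family`, `genus`,
#'   `species_epithet`, `count` (non-negative integers). Every `deposit_id`
#'   must occur in `deposits`.
#' @return an object of class `fecal_deposits`: a list with elements
#'   `deposits` and `seeds`.
#' @export
fecal_deposits <- function(deposits, seeds = NULL) {
  deposits <- as.data.frame(deposits, stringsAsFactors = FALSE)
  required <- c("deposit_id", "site", "date", "species", "x_m", "y_m",
                "shrub_cover_pct", "sample_dw_g")
  missing_cols <- setdiff(required, names(deposits))
  if (length(missing_cols))
    stop("deposits table is missing columns: ", paste(missing_cols, collapse = ", "))
  deposits$deposit_id <- as.character(deposits$deposit_id)
  if (anyDuplicated(deposits$deposit_id))
    stop("duplicate deposit_id values in deposits table")
  bad <- which(!deposits$species %in% UNGULATE_SPECIES)
  if (length(bad))
    stop(sprintf("unknown species '%s' in deposits row %d (expected one of %s)",
                 deposits$species[bad[1]], bad[1],
                 paste(UNGULATE_SPECIES, collapse = ", ")))
  for (col in c("x_m", "y_m")) {
    v <- deposits[[col]]
    if (!all(is.finite(v)))
      stop(sprintf("non-finite coordinate in column '%s' (row %d)",
                   col, which(!is.finite(v))[1]))
  }
  sc <- deposits$shrub_cover_pct
  if (any(!is.na(sc) & (sc < 0 | sc > 100)))
    stop("shrub_cover_pct outside [0, 100]")
  dw <- deposits$sample_dw_g
  if (any(!is.na(dw) & dw <= 0))
    stop("sample_dw_g must be > 0 when present")

  if (is.null(seeds)) {
    seeds <- data.frame(deposit_id = character(), family = character(),
                        genus = character(), species_epithet = character(),
                        count = integer(), stringsAsFactors = FALSE)
  } else {
    seeds <- as.data.frame(seeds, stringsAsFactors = FALSE)
    req_s <- c("deposit_id", "family", "count")
    missing_s <- setdiff(req_s, names(seeds))
    if (length(missing_s))
      stop("seeds table is missing columns: ", paste(missing_s, collapse = ", "))
    if (is.null(seeds$genus)) seeds$genus <- ""
    if (is.null(seeds$species_epithet)) seeds$species_epithet <- ""
    seeds$deposit_id <- as.character(seeds$deposit_id)
    orphan <- which(!seeds$deposit_id %in% deposits$deposit_id)
    if (length(orphan))
      stop(sprintf("seeds row %d references unknown deposit_id '%s'",
                   orphan[1], seeds$deposit_id[orphan[1]]))
    if (any(is.na(seeds$count) | seeds$count < 0))
      stop("seed counts must be non-negative")
    seeds$count <- as.integer(seeds$count)
  }
  structure(list(deposits = deposits, seeds = seeds), class = "fecal_deposits")
}

#' @export
print.fecal_deposits <- function(x, ...) {
  cat(sprintf("fecal_deposits: %d deposits, %d seed records, %d seeds total\n",
              nrow(x$deposits), nrow(x$seeds), sum(x$seeds$count)))
  tab <- table(x$deposits$species)
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Read fecal-deposit and seed-count tables
#'
#' Reads the two-file CSV layout: a deposits table (one fecal unit per row)
#' and a long-format seed-count table keyed by `deposit_id`. Seed taxa absent
#' from a deposit implicitly have count 0.
#'
#' @param deposits_path path to `deposits.csv` with the documented header
#'   (`deposit_id,site,date,species,x_m,y_m,shrub_cover_pct,sample_dw_g`).
#' @param seeds_path path to `seeds.csv`
#'   (`deposit_id,family,genus,species_epithet,count`).
#' @return a [fecal_deposits()] object, deposit row order preserved.
#' @export
read_deposits <- function(deposits_path, seeds_path) {
  if (!file.exists(deposits_path)) stop("deposits file not found: ", deposits_path)
  if (!file.exists(seeds_path)) stop("seeds file not found: ", seeds_path)
  dep <- utils::read.csv(deposits_path, stringsAsFactors = FALSE,
                         colClasses = c(deposit_id = "character"))
  sds <- utils::read.csv(seeds_path, stringsAsFactors = FALSE)
  if (nrow(sds) > 0) sds$deposit_id <- as.character(sds$deposit_id)
  fecal_deposits(dep, if (nrow(sds)) sds else NULL)
}

#' Write fecal-deposit and seed-count tables
#'
#' Inverse of [read_deposits()]; round-trips all fields.
#'
#' @param x a `fecal_deposits` object.
#' @param deposits_path,seeds_path output CSV paths.
#' @return `x`, invisibly.
#' @export
write_deposits <- function(x, deposits_path, seeds_path) {
  stopifnot(inherits(x, "fecal_deposits"))
  utils::write.csv(x$deposits, deposits_path, row.names = FALSE)
  utils::write.csv(x$seeds, seeds_path, row.names = FALSE)
  invisible(x)
}

#' Per-deposit seed counts aggregated to family level
#'
#' @param x a `fecal_deposits` object.
#' @return integer matrix, one row per deposit (rownames = deposit_id), one
#'   column per normalized family key including `"unidentified"` when present.
#' @export
seed_count_matrix <- function(x) {
  stopifnot(inherits(x, "fecal_deposits"))
  ids <- x$deposits$deposit_id
  if (nrow(x$seeds) == 0) {
    m <- matrix(0L, nrow = length(ids), ncol = 0)
    rownames(m) <- ids
    return(m)
  }
  fam <- normalize_taxon(x$seeds$family)
  fams <- sort(unique(fam))
  m <- matrix(0L, nrow = length(ids), ncol = length(fams),
              dimnames = list(ids, fams))
  i <- match(x$seeds$deposit_id, ids)
  j <- match(fam, fams)
  for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + x$seeds$count[k]
  m
}

#' Total seeds counted per deposit (raw counts, all taxa)
#'
#' @param x a `fecal_deposits` object.
#' @return named integer vector, one entry per deposit.
#' @export
total_seed_counts <- function(x) {
  m <- seed_count_matrix(x)
  if (ncol(m) == 0) return(stats::setNames(integer(nrow(x$deposits)),
                                           x$deposits$deposit_id))
  rowSums(m)
}

#' Project longitude/latitude to local planar meters
#'
#' Local equirectangular projection about a reference point on a sphere of
#' radius 6,371,000 m: `x = R cos(lat_ref) dlon`, `y = R dlat` (angles in
#' radians). Adequate for plots a few kilometers across; refuses spans of a
#' degree or more.
#'
#' @param lonlat two-column matrix or data frame of (longitude, latitude)
#'   in decimal degrees.
#' @param reference length-2 numeric `(lon, lat)` mapped to (0, 0).
#' @return two-column matrix of (x, y) in meters.
#' @export
project_lonlat <- function(lonlat, reference) {
  lonlat <- as.matrix(lonlat)
  stopifnot(ncol(lonlat) == 2, length(reference) == 2)
  if (abs(reference[2]) >= 89 || any(abs(lonlat[, 2]) >= 89))
    stop("project_lonlat: latitudes must satisfy |lat| < 89 degrees")
  span <- max(apply(rbind(lonlat, reference), 2, function(v) diff(range(v))))
  if (span >= 1)
    stop("project_lonlat: coordinate span >= 1 degree; use a proper projected CRS")
  R <- 6371000
  rad <- pi / 180
  cbind(x = R * cos(reference[2] * rad) * (lonlat[, 1] - reference[1]) * rad,
        y = R * (lonlat[, 2] - reference[2]) * rad)
}

#' Quantitatively marked point pattern
#'
#' Planar points in a rectangular window, each carrying one non-negative
#' quantitative mark (here: estimated seed content per fecal unit).
#'
#' @param x,y numeric coordinate vectors (meters).
#' @param marks numeric vector of non-negative marks, same length.
#' @param window a [study_window()], or `"auto"` for the bounding box of the
#'   points.
#' @return an object of class `marked_pattern` with fields `x`, `y`, `marks`,
#'   `n`, `window`.
#' @export
marked_pattern <- function(x, y, marks, window = "auto") {
  stopifnot(length(x) == length(y), length(x) == length(marks))
  if (length(x) < 2) stop("marked_pattern: need at least 2 points")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("marked_pattern: coordinates must be finite")
  if (!all(is.finite(marks)) || any(marks < 0))
    stop("marked_pattern: marks must be finite and non-negative")
  if (identical(window, "auto")) {
    pad <- function(r) if (diff(r) > 0) r else r + c(-0.5, 0.5)
    rx <- pad(range(x)); ry <- pad(range(y))
    window <- study_window(rx[1], rx[2], ry[1], ry[2])
  }
  stopifnot(inherits(window, "study_window"))
  inside <- x >= window$x_min & x <= window$x_max &
    y >= window$y_min & y <= window$y_max
  if (!all(inside))
    stop(sprintf("marked_pattern: point %d lies outside the window",
                 which(!inside)[1]))
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 marks = as.numeric(marks), n = length(x), window = window),
            class = "marked_pattern")
}

#' @export
print.marked_pattern <- function(x, ...) {
  cat(sprintf("marked_pattern: n = %d, mark mean = %.3g, window %.2f ha\n",
              x$n, mean(x$marks), x$window$area_ha))
  invisible(x)
}

#' Build a marked point pattern from fecal deposits
#'
#' Marks are per-fecal-unit seed estimates: standardized seed content
#' (seeds per gram dry weight) multiplied by the species' mean dung dry
#' weight per defecation. Deposits lacking a sample dry weight are dropped
#' with a warning; the number of exclusions is attached as attribute
#' `"excluded"`.
#'
#' @param x a `fecal_deposits` object.
#' @param mark_source `"total"` for all seeds, or `"family"` with `family=`
#'   naming one plant family (marks restricted to that family's seeds; a
#'   family absent from every deposit yields all-zero marks).
#' @param family family name when `mark_source = "family"`.
#' @param window a [study_window()] or `"auto"` (bounding box).
#' @param dung a [dung_weight_table()].
#' @return a [marked_pattern()]; attribute `"excluded"` counts dropped
#'   deposits, attribute `"deposit_id"` holds the ids of retained ones.
#' @export
to_marked_pattern <- function(x, mark_source = c("total", "family"),
                              family = NULL, window = "auto",
                              dung = dung_weight_table()) {
  stopifnot(inherits(x, "fecal_deposits"))
  mark_source <- match.arg(mark_source)
  if (mark_source == "family" && is.null(family))
    stop("mark_source = 'family' requires a family name")

  dep <- x$deposits
  keep <- !is.na(dep$sample_dw_g)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    warning(sprintf("excluding %d deposit(s) lacking sample dry weight", n_excluded))
  dep <- dep[keep, , drop = FALSE]
  if (nrow(dep) < 2)
    stop("fewer than 2 deposits with sample dry weight; cannot build a pattern")

  counts <- seed_count_matrix(x)[keep, , drop = FALSE]
  if (mark_source == "total") {
    cnt <- if (ncol(counts)) rowSums(counts) else numeric(nrow(dep))
  } else {
    key <- normalize_taxon(family)
    cnt <- if (key %in% colnames(counts)) counts[, key] else numeric(nrow(dep))
  }
  spg <- standardize_seed_content(cnt, dep$sample_dw_g)
  marks <- per_fecal_unit(spg, dep$species, dung)

  pat <- marked_pattern(dep$x_m, dep$y_m, marks, window = window)
  attr(pat, "excluded") <- n_excluded
  attr(pat, "deposit_id") <- dep$deposit_id
  pat
}

#' Export a marked pattern as a tidy data frame
#'
#' @param pattern a `marked_pattern`.
#' @return data frame with columns `x`, `y`, `mark`.
#' @export
pattern_as_df <- function(pattern) {
  stopifnot(inherits(pattern, "marked_pattern"))
  data.frame(x = pattern$x, y = pattern$y, mark = pattern$marks)
}
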