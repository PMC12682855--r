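#' Describe a two-level phosphorus trial
#'
#' A trial design records the genotype panel, the two P levels, the mass of P
#' made available to each tube under each level, and the replication. It is
#' the anchor against which harvest tables are validated and the source of the
#' P-applied denominators used by [pae()] and [apue()].
#'
#' @param genotypes Character vector of genotype labels (unique, non-empty).
#' @param p_levels Exactly two level labels; the first is the high-P
#'   (optimal) level, the second the low-P (deficient) level.
#' @param p_applied Named numeric vector (names = `p_levels`): grams of P
#'   available per tube under each level. The high level must exceed the low
#'   level and both must be positive. Defaults approximate a Hoagland supply
#'   of 0.3 mM versus 0.0032 mM NH4H2PO4 delivered over a four-week trial.
#' @param replicates_per_cell Positive integer, tubes per genotype x level.
#' @param platform_label Free-text label of the phenotyping platform.
#'
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(genotypes,
                         p_levels = c("P+", "P-"),
                         p_applied = c("P+" = 0.130, "P-" = 0.0014),
                         replicates_per_cell = 6L,
                         platform_label = "generic") {
  genotypes <- as.character(genotypes)
  if (length(genotypes) < 1L || anyDuplicated(genotypes) || any(!nzchar(genotypes)))
    stop("`genotypes` must be non-empty, unique labels")
  if (length(p_levels) != 2L || anyDuplicated(p_levels))
    stop("exactly two distinct P levels are required")
  if (!all(p_levels %in% names(p_applied)))
    stop("`p_applied` must be named by the two P levels")
  p_applied <- p_applied[p_levels]
  if (any(p_applied <= 0) || p_applied[[1L]] <= p_applied[[2L]])
    stop("P applied must satisfy high > low > 0 (first level is the high one)")
  replicates_per_cell <- as.integer(replicates_per_cell)
  if (is.na(replicates_per_cell) || replicates_per_cell < 1L)
    stop("`replicates_per_cell` must be a positive integer")
  structure(
    list(genotypes = genotypes, p_levels = p_levels, p_applied = p_applied,
         replicates_per_cell = replicates_per_cell,
         platform_label = as.character(platform_label)[1L]),
    class = "trial_design")
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Trial design [", x$platform_label, "]: ",
      length(x$genotypes), " genotypes x ", length(x$p_levels),
      " P levels x ", x$replicates_per_cell, " replicates\n", sep = "")
  cat("P applied (g/tube): ",
      paste(sprintf("%s = %g", x$p_levels, x$p_applied), collapse = ", "), "\n")
  invisible(x)
}

harvest_columns <- c("genotype", "p_level", "replicate", "shoot_dw", "root_dw",
                     "plant_p_concentration", "p_uptake")
harvest_optional <- c("height", "culms")

#' Read and validate a harvest table
#'
#' Reads a CSV of per-tube harvest observations (one row = one tube at
#' harvest) and validates every row against a [trial_design()]: genotype and
#' P-level labels must belong to the design and measurements must be
#' non-negative. Optional columns (`height`, `culms`) are kept when present
#' and stored as missing otherwise, never imputed.
#'
#' @param path Path to a CSV file with a header row naming at least
#'   `r paste(harvest_columns, collapse = ", ")`.
#' @param design A [trial_design()].
#' @param col_map Optional named character vector remapping external headers
#'   to the canonical names, e.g. `c(shoot_dw = "ShootDW_g")`.
#'
#' @return A tibble with one row per harvest record, in file order.
#' @export
read_harvest_table <- function(path, design, col_map = NULL) {
  stopifnot(inherits(design, "trial_design"))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      ext <- col_map[[canon]]
      if (ext %in% names(tbl)) names(tbl)[names(tbl) == ext] <- canon
    }
  }
  missing_cols <- setdiff(harvest_columns, names(tbl))
  if (length(missing_cols))
    stop("harvest table is missing columns: ", paste(missing_cols, collapse = ", "))
  for (opt in harvest_optional) {
    if (!opt %in% names(tbl)) tbl[[opt]] <- NA_real_
    tbl[[opt]] <- as.numeric(tbl[[opt]])  # all-NA columns parse as logical
  }
  tbl <- tbl[, c(harvest_columns, harvest_optional)]
  if (nrow(tbl) == 0L) {
    warning("harvest table at '", path, "' contains a header but no records")
    return(tibble::as_tibble(tbl))
  }
  validate_harvest(tbl, design)
  tibble::as_tibble(tbl)
}

validate_harvest <- function(tbl, design) {
  bad_geno <- which(!tbl$genotype %in% design$genotypes)
  if (length(bad_geno))
    stop("row ", bad_geno[1L], ": unknown genotype '", tbl$genotype[bad_geno[1L]],
         "' not in trial design")
  bad_level <- which(!tbl$p_level %in% design$p_levels)
  if (length(bad_level))
    stop("row ", bad_level[1L], ": unknown P level '", tbl$p_level[bad_level[1L]], "'")
  for (col in c("shoot_dw", "root_dw", "plant_p_concentration", "p_uptake")) {
    bad <- which(!is.na(tbl[[col]]) & tbl[[col]] < 0)
    if (length(bad))
      stop("row ", bad[1L], ": negative value in '", col, "'")
  }
  invisible(tbl)
}

#' Write a harvest table to CSV
#'
#' @param tbl A harvest tibble as returned by [read_harvest_table()] or
#'   [simulate_trial()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_harvest_table <- function(tbl, path) {
  readr::write_csv(tbl, path)
  invisible(path)
}

metric_table_columns <- c(
  "genotype",
  "pae_pminus_mean", "pae_pminus_sd", "prae_pminus_mean", "prae_pminus_sd",
  "pue_pminus_mean", "pue_pminus_sd",
  "pae_pplus_mean", "pae_pplus_sd", "prae_pplus_mean", "prae_pplus_sd",
  "pue_pplus_mean", "pue_pplus_sd",
  "relative_efficiency", "apue")

#' Construct a genotype-level metric table
#'
#' One row per genotype; PAE/PRAE/PUE are held as mean and sample SD per P
#' level (column suffixes `pplus`/`pminus`), while P relative efficiency and
#' APUE are level-free scalars, mirroring how large-trial summaries print
#' them. Mostly used internally; [compute_metric_table()] and
#' [load_table3()] return objects of this class.
#'
#' @param df Data frame with the canonical metric columns.
#' @param platform Platform label.
#' @param n Replicates per cell behind the means (may be `NA`).
#' @return A tibble of class `metric_table` with attributes `platform`, `n`.
#' @export
metric_table <- function(df, platform = "generic", n = NA_integer_) {
  missing_cols <- setdiff(metric_table_columns, names(df))
  if (length(missing_cols))
    stop("metric table is missing columns: ", paste(missing_cols, collapse = ", "))
  df <- tibble::as_tibble(df[, metric_table_columns])
  if (anyDuplicated(df$genotype)) stop("one row per genotype is required")
  sd_cols <- grep("_sd$", names(df), value = TRUE)
  for (col in sd_cols)
    if (any(!is.na(df[[col]]) & df[[col]] < 0)) stop("negative SD in '", col, "'")
  structure(df, platform = as.character(platform)[1L], n = n,
            class = c("metric_table", class(df)))
}

#' Load the packaged large-trial metric tables
#'
#' Returns the published genotype-level five-metric summary for one of the two
#' phenotyping platforms (26 bread wheat genotypes each): `"4PMI"` (Dijon,
#' inert substrate, 28-day trial, n = 6) or `"ALSIA"` (Metaponto, P-free
#' soil, 96-day trial, n = 4). Values are transcribed at their printed
#' precision; no re-rounding is applied.
#'
#' @param platform `"4PMI"` or `"ALSIA"`.
#' @return A [metric_table()].
#' @export
load_table3 <- function(platform = c("4PMI", "ALSIA")) {
  platform <- match.arg(platform)
  file <- system.file("extdata",
                      if (platform == "4PMI") "table3_4pmi.csv" else "table3_alsia.csv",
                      package = "pindicator", mustWork = TRUE)
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  metric_table(df, platform = platform, n = if (platform == "4PMI") 6L else 4L)
}

#' Write / read metric tables
#'
#' CSV round-trip for [metric_table()] objects; the column layout mirrors the
#' published summary tables (per-level mean/SD triplets then the two
#' level-free scalars).
#'
#' @param tbl A `metric_table`.
#' @param path CSV path.
#' @return `write_metric_table()` returns `path` invisibly;
#'   `read_metric_table()` returns a `metric_table`.
#' @export
write_metric_table <- function(tbl, path) {
  stopifnot(inherits(tbl, "metric_table"))
  readr::write_csv(tibble::as_tibble(tbl), path)
  invisible(path)
}

#' @rdname write_metric_table
#' @param platform,n Metadata to attach on read (see [metric_table()]).
#' @export
read_metric_table <- function(path, platform = "generic", n = NA_integer_) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  metric_table(df, platform = platform, n = n)
}

# Map a level label to the column suffix used in metric tables: the first
# (high) design level is "pplus", the second "pminus".
level_suffix <- function(level, p_levels = c("P+", "P-")) {
  if (level == p_levels[[1L]]) "pplus" else if (level == p_levels[[2L]]) "pminus"
  else stop("unknown P level '", level, "'")
}
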