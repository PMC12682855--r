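#' Min-max normalize a vector to [0, 1]
#'
#' Affine rescaling sending the minimum to 0 and the maximum to 1. A
#' constant vector has no usable range and is mapped to all 0.5 with a
#' warning (every genotype is equally mid-scale rather than arbitrarily best
#' or worst).
#'
#' @param values Numeric vector, length >= 2, all finite.
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(values) {
  if (length(values) < 2L) stop("need at least two values to normalize")
  bad <- which(!is.finite(values))
  if (length(bad))
    stop("non-finite value at position ", bad[1L])
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    warning("constant input: min-max range is zero, returning 0.5 for all")
    return(rep(0.5, length(values)))
  }
  (values - rng[1L]) / (rng[2L] - rng[1L])
}

# 0-1 normalization of ranks; robust alternative when metric values carry
# limited resolution (e.g. tables printed at coarse precision).
rank_normalize <- function(values) {
  minmax_normalize(rank(values, ties.method = "average"))
}

#' Compute the composite 0-5 P indicator
#'
#' Builds the synthetic "P indicator" from a genotype-level [metric_table()]:
#' the five components (PAE, PRAE and PUE at the chosen P level, plus the
#' level-free P relative efficiency and APUE) are each normalized to
#' `[0, 1]` across genotypes and summed, giving a score between 0 (lowest
#' overall efficiency) and 5 (best-performing genotype). All five components
#' are treated as higher-is-better. Genotypes missing any of the five
#' metrics are excluded with a warning and normalization runs over the
#' remainder.
#'
#' @param table A [metric_table()].
#' @param condition P level whose PAE/PRAE/PUE enter the indicator: `"P-"`
#'   (default; the indicator targets performance under deficiency) or `"P+"`.
#' @param normalization `"minmax"` (the defining construction) or `"rank"`
#'   (min-max of average ranks; identical bounds, robust to coarse printed
#'   precision of the inputs).
#' @return A tibble of class `indicator_result` with the five normalized
#'   components, `score` in `[0, 5]` and dense `rank` (1 = best), plus
#'   attributes `condition`, `platform` and `normalization`.
#' @export
compute_indicator <- function(table, condition = c("P-", "P+"),
                              normalization = c("minmax", "rank")) {
  stopifnot(inherits(table, "metric_table"))
  condition <- match.arg(condition)
  normalization <- match.arg(normalization)
  suffix <- if (condition == "P-") "pminus" else "pplus"
  cols <- c(paste0(c("pae_", "prae_", "pue_"), suffix, "_mean"),
            "relative_efficiency", "apue")
  df <- tibble::as_tibble(table)[, c("genotype", cols)]
  names(df) <- c("genotype", "pae", "prae", "pue", "pre", "apue")
  keep <- stats::complete.cases(df)
  if (!all(keep)) {
    warning("excluding genotype(s) with missing metrics: ",
            paste(df$genotype[!keep], collapse = ", "))
    df <- df[keep, ]
  }
  if (nrow(df) < 2L) stop("need at least two complete genotypes")
  norm <- if (normalization == "minmax") minmax_normalize else rank_normalize
  out <- tibble::tibble(
    genotype = df$genotype,
    pae_norm = norm(df$pae),
    prae_norm = norm(df$prae),
    pue_norm = norm(df$pue),
    pre_norm = norm(df$pre),
    apue_norm = norm(df$apue))
  out$score <- out$pae_norm + out$prae_norm + out$pue_norm +
    out$pre_norm + out$apue_norm
  out$rank <- dplyr::dense_rank(dplyr::desc(out$score))
  structure(out,
            condition = condition,
            platform = attr(table, "platform"),
            normalization = normalization,
            class = c("indicator_result", class(out)))
}

#' Classify genotypes into efficiency/responsiveness quadrants
#'
#' Crosses efficiency (whole-plant dry weight under P deficiency) with
#' responsiveness to P supply (APUE), splitting at a threshold computed
#' across genotypes (mean by default, as in the coffee-trial classification
#' this scheme follows; median optional). Classes: ER (efficient and
#' responsive), ENR (efficient, non-responsive), NER (non-efficient,
#' responsive), NENR (neither). Genotypes sitting exactly on a threshold are
#' classified into the upper class (`>=` convention, deterministic).
#'
#' @param apue Named numeric vector of per-genotype APUE values.
#' @param dw_pminus Named numeric vector of per-genotype genotype-mean
#'   whole-plant dry weight at the low P level; names must match `apue`.
#' @param rule `"mean"` or `"median"`: how both thresholds are computed.
#' @return A tibble of class `quadrant_classification` with columns
#'   `genotype`, `apue`, `dw_pminus`, `class`, and attributes
#'   `apue_threshold`, `dw_threshold`, `rule`.
#' @export
classify_quadrants <- function(apue, dw_pminus, rule = c("mean", "median")) {
  rule <- match.arg(rule)
  if (is.null(names(apue)) || is.null(names(dw_pminus)))
    stop("`apue` and `dw_pminus` must be named by genotype")
  only_a <- setdiff(names(apue), names(dw_pminus))
  only_d <- setdiff(names(dw_pminus), names(apue))
  if (length(only_a) || length(only_d))
    stop("genotype sets differ; only in apue: {",
         paste(only_a, collapse = ", "), "}; only in dw: {",
         paste(only_d, collapse = ", "), "}")
  dw_pminus <- dw_pminus[names(apue)]
  thr <- function(x) if (rule == "mean") mean(x) else stats::median(x)
  t_a <- thr(apue); t_d <- thr(dw_pminus)
  responsive <- apue >= t_a
  efficient <- dw_pminus >= t_d
  cls <- unname(ifelse(responsive & efficient, "ER",
                ifelse(!responsive & efficient, "ENR",
                ifelse(responsive & !efficient, "NER", "NENR"))))
  structure(
    tibble::tibble(genotype = names(apue), apue = unname(apue),
                   dw_pminus = unname(dw_pminus), class = cls),
    apue_threshold = t_a, dw_threshold = t_d, rule = rule,
    class = c("quadrant_classification", class(tibble::tibble())))
}
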