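#' Phosphorus acquisition efficiency (PAE)
#'
#' Percentage of the supplied P that the plant took up:
#' `PAE = P_uptake / P_applied * 100`. Scale-invariant under joint rescaling
#' of uptake and supply, so the per-tube versus per-litre basis of the
#' denominator cancels as long as uptake is expressed on the same basis.
#'
#' @param p_uptake Grams of P in the whole plant (>= 0).
#' @param p_applied Grams of P made available (> 0).
#' @return PAE as a percentage (vectorised).
#' @export
pae <- function(p_uptake, p_applied) {
  if (any(p_applied <= 0)) stop("`p_applied` must be > 0")
  if (any(p_uptake < 0)) stop("`p_uptake` must be >= 0")
  p_uptake / p_applied * 100
}

#' Phosphorus utilization efficiency (PUE, balance method)
#'
#' `PUE = DW / P_concentration * DW`, i.e. squared dry weight over tissue P
#' concentration. The squared-biomass form is the balance-method definition
#' used in large phenotyping trials; its units (g^2 per concentration unit)
#' are unusual but the formula is implemented literally, and the
#' concentration unit is carried through unchanged.
#'
#' @param dry_weight Plant dry weight in g (>= 0).
#' @param p_concentration Tissue P concentration (> 0), conventionally mM.
#' @return PUE score (vectorised).
#' @export
pue <- function(dry_weight, p_concentration) {
  if (any(p_concentration <= 0)) stop("`p_concentration` must be > 0")
  if (any(dry_weight < 0)) stop("`dry_weight` must be >= 0")
  dry_weight^2 / p_concentration
}

#' Phosphorus root acquisition efficiency (PRAE)
#'
#' Grams of P acquired per gram of root biomass:
#' `PRAE = P_uptake / RootBiomass`.
#'
#' @param p_uptake Grams of P in the whole plant (>= 0).
#' @param root_biomass Root dry weight in g (> 0).
#' @return PRAE (vectorised).
#' @export
prae <- function(p_uptake, root_biomass) {
  if (any(root_biomass <= 0)) stop("`root_biomass` must be > 0")
  if (any(p_uptake < 0)) stop("`p_uptake` must be >= 0")
  p_uptake / root_biomass
}

#' Agronomic phosphorus use efficiency (APUE)
#'
#' Extra dry matter produced per extra unit of available P between the
#' optimal and deficient treatments:
#' `APUE = (DW_P+ - DW_P-) / (available_P+ - available_P-)`.
#' Dry weights are genotype means; a negative response (more biomass under
#' deficiency) is preserved, not clamped.
#'
#' @param dw_pplus,dw_pminus Genotype-mean dry weights (g) at the high and
#'   low P level.
#' @param avail_pplus,avail_pminus Total available P (g) at each level;
#'   the high level must exceed the low one.
#' @return APUE in g dry weight per g P (vectorised).
#' @export
apue <- function(dw_pplus, dw_pminus, avail_pplus, avail_pminus) {
  if (any(avail_pplus <= avail_pminus))
    stop("available P must satisfy P+ > P-")
  (dw_pplus - dw_pminus) / (avail_pplus - avail_pminus)
}

#' Phosphorus relative efficiency (PRE)
#'
#' Biomass at the low P level as a percentage of biomass at the optimal
#' level: `PRE = Biomass_P- / Biomass_P+ * 100`. A value of 100 means no
#' biomass penalty under deficiency; it is a plasticity/tolerance measure.
#'
#' @param biomass_pminus Biomass at low P (g, >= 0).
#' @param biomass_pplus Biomass at optimal P (g, > 0).
#' @return PRE as a percentage (vectorised).
#' @export
relative_efficiency <- function(biomass_pminus, biomass_pplus) {
  if (any(biomass_pplus <= 0)) stop("`biomass_pplus` must be > 0")
  if (any(biomass_pminus < 0)) stop("`biomass_pminus` must be >= 0")
  biomass_pminus / biomass_pplus * 100
}

#' Configuration for metric aggregation
#'
#' @param concentration_unit Label for the tissue concentration unit carried
#'   through [pue()]; informational only, never converted.
#' @param aggregation Only `"replicate-then-mean"` is supported: PAE/PRAE/PUE
#'   are computed per replicate and then summarised as mean +/- sample SD.
#' @param apue_on_means APUE and PRE are computed from genotype-mean dry
#'   weights (the convention behind published tables, which print them
#'   without SD).
#' @param dw_basis Dry-weight basis for PUE/APUE/PRE: `"total"` (shoot +
#'   root, the default, since the defining formulas name whole-plant dry
#'   weight) or `"shoot"`.
#' @return A list of class `metric_config`.
#' @export
metric_config <- function(concentration_unit = "mM",
                          aggregation = "replicate-then-mean",
                          apue_on_means = TRUE,
                          dw_basis = c("total", "shoot")) {
  aggregation <- match.arg(aggregation, "replicate-then-mean")
  dw_basis <- match.arg(dw_basis)
  structure(list(concentration_unit = concentration_unit,
                 aggregation = aggregation,
                 apue_on_means = apue_on_means,
                 dw_basis = dw_basis),
            class = "metric_config")
}

#' Aggregate harvest records into a genotype-level metric table
#'
#' Computes the five P-efficiency metrics from per-tube harvest records:
#' PAE, PRAE and PUE per replicate, summarised as mean and sample (n-1) SD
#' per genotype x P level; APUE and P relative efficiency once per genotype
#' from genotype-mean dry weight. A genotype missing one P level keeps its
#' per-level summaries but has `NA` APUE/PRE (with a warning).
#'
#' @param records Harvest tibble (see [read_harvest_table()]).
#' @param design The [trial_design()] providing P-applied denominators.
#' @param cfg A [metric_config()].
#' @return A [metric_table()].
#' @export
compute_metric_table <- function(records, design, cfg = metric_config()) {
  stopifnot(inherits(design, "trial_design"))
  validate_harvest(records, design)
  high <- design$p_levels[[1L]]; low <- design$p_levels[[2L]]

  dw_for <- function(shoot, root) {
    if (cfg$dw_basis == "total") shoot + root else shoot
  }

  per_rep <- records |>
    dplyr::mutate(
      .dw = dw_for(.data$shoot_dw, .data$root_dw),
      .pae = pae(.data$p_uptake, unname(design$p_applied[.data$p_level])),
      .prae = prae(.data$p_uptake, .data$root_dw),
      .pue = pue(.data$.dw, .data$plant_p_concentration))

  sample_sd <- function(x) if (length(x) < 2L) NA_real_ else stats::sd(x)
  by_cell <- per_rep |>
    dplyr::group_by(.data$genotype, .data$p_level) |>
    dplyr::summarise(
      pae_mean = mean(.data$.pae), pae_sd = sample_sd(.data$.pae),
      prae_mean = mean(.data$.prae), prae_sd = sample_sd(.data$.prae),
      pue_mean = mean(.data$.pue), pue_sd = sample_sd(.data$.pue),
      dw_mean = mean(.data$.dw), n = dplyr::n(), .groups = "drop")

  wide <- by_cell |>
    dplyr::mutate(suffix = vapply(.data$p_level, level_suffix, "",
                                  p_levels = design$p_levels)) |>
    dplyr::select(-"p_level") |>
    tidyr::pivot_wider(names_from = "suffix",
                       values_from = c("pae_mean", "pae_sd", "prae_mean", "prae_sd",
                                       "pue_mean", "pue_sd", "dw_mean", "n"),
                       names_glue = "{.value}_{suffix}")
  # rename mean_<suffix> style to the canonical <metric>_<suffix>_<stat>
  canon <- function(metric, stat, suffix) paste0(metric, "_", suffix, "_", stat)
  for (metric in c("pae", "prae", "pue")) for (stat in c("mean", "sd"))
    for (suffix in c("pplus", "pminus")) {
      old <- paste0(metric, "_", stat, "_", suffix)
      if (old %in% names(wide)) names(wide)[names(wide) == old] <- canon(metric, stat, suffix)
    }
  for (suffix in c("pplus", "pminus")) {
    for (col in paste0(c("dw_mean_", "n_"), suffix))
      if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }

  incomplete <- is.na(wide$dw_mean_pplus) | is.na(wide$dw_mean_pminus)
  if (any(incomplete))
    warning("genotype(s) missing one P level, APUE/PRE set NA: ",
            paste(wide$genotype[incomplete], collapse = ", "))
  wide$apue <- ifelse(incomplete, NA_real_,
                      apue(wide$dw_mean_pplus, wide$dw_mean_pminus,
                           design$p_applied[[high]], design$p_applied[[low]]))
  wide$relative_efficiency <- ifelse(incomplete, NA_real_,
                                     wide$dw_mean_pminus / wide$dw_mean_pplus * 100)

  out <- wide[match(intersect(design$genotypes, wide$genotype), wide$genotype), ]
  n_cell <- suppressWarnings(stats::median(c(out$n_pplus, out$n_pminus), na.rm = TRUE))
  res <- metric_table(out, platform = design$platform_label,
                      n = as.integer(n_cell))
  attr(res, "dw_mean_pminus") <- stats::setNames(out$dw_mean_pminus, out$genotype)
  attr(res, "dw_mean_pplus") <- stats::setNames(out$dw_mean_pplus, out$genotype)
  res
}
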