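#' Configuration for the factorial trial generator
#'
#' Defaults emulate the structure of the two-platform wheat trials: a
#' 26-genotype x 2-P-level randomized design with 6 tubes per cell (the
#' 4-replicate variant mirrors the second platform), multiplicative
#' (log-normal) noise on biomass and tissue concentration, a shared latent
#' genotype efficiency driving all five metrics, and a genotype x treatment
#' interaction. Baseline means are set so that the simulated metric ranges
#' bracket the published large-trial ranges (e.g. PAE roughly 10-90).
#'
#' @param n_genotypes Number of genotypes (default 26).
#' @param replicates Tubes per genotype x level (default 6; use 4 for the
#'   smaller platform).
#' @param p_applied Named grams of P available per tube (high then low).
#' @param shoot_dw_mean Baseline shoot dry weight (g) per level.
#' @param root_shoot_ratio Root:shoot dry-weight ratio per level (deficiency
#'   shifts allocation towards roots).
#' @param pconc_frac Baseline tissue P mass fraction (g P per g DW) per
#'   level.
#' @param conc_unit_factor Factor converting the mass fraction to the
#'   concentration unit stored on records (nominally mM).
#' @param genotype_effect Log-scale slope of the latent genotype efficiency
#'   on dry weight, per level; larger under deficiency so that tolerant
#'   genotypes lose less biomass (this is what makes PRE informative).
#' @param conc_effect Log-scale slope of the latent efficiency on tissue P
#'   concentration (efficient acquirers carry more P).
#' @param interaction_sd SD of the genotype x level log-scale interaction.
#' @param cv Residual coefficient of variation of the multiplicative noise.
#' @param rho_true Latent cross-platform correlation used by
#'   [simulate_paired_platforms()].
#' @param platform_label Label stamped on generated designs.
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genotypes = 26L,
                              replicates = 6L,
                              p_applied = c("P+" = 0.130, "P-" = 0.0014),
                              shoot_dw_mean = c("P+" = 2.0, "P-" = 0.35),
                              root_shoot_ratio = c("P+" = 0.5, "P-" = 0.6),
                              pconc_frac = c("P+" = 0.013, "P-" = 0.0012),
                              conc_unit_factor = 5,
                              genotype_effect = c("P+" = 0.10, "P-" = 0.25),
                              conc_effect = 0.05,
                              interaction_sd = 0.05,
                              cv = 0.10,
                              rho_true = 0.45,
                              platform_label = "SIM",
                              seed) {
  if (missing(seed) || is.na(suppressWarnings(as.integer(seed))))
    stop("an integer `seed` is mandatory")
  stopifnot(n_genotypes >= 2L, replicates >= 1L,
            interaction_sd >= 0, cv >= 0,
            rho_true >= 0, rho_true <= 1)
  structure(list(n_genotypes = as.integer(n_genotypes),
                 replicates = as.integer(replicates),
                 p_applied = p_applied, shoot_dw_mean = shoot_dw_mean,
                 root_shoot_ratio = root_shoot_ratio, pconc_frac = pconc_frac,
                 conc_unit_factor = conc_unit_factor,
                 genotype_effect = genotype_effect, conc_effect = conc_effect,
                 interaction_sd = interaction_sd, cv = cv,
                 rho_true = rho_true, platform_label = platform_label,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

sim_genotype_labels <- function(n) sprintf("G%02d", seq_len(n))

# Log-normal noise SD matched to a coefficient of variation.
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# Core record generator: given latent efficiencies and interaction effects,
# produce `replicates` records per cell, with or without residual noise.
generate_records <- function(cfg, latent, gamma, noisy = TRUE) {
  levels <- c("P+", "P-")
  genos <- names(latent)
  sdlog <- if (noisy) cv_to_sdlog(cfg$cv) else 0
  grid <- expand.grid(replicate = seq_len(cfg$replicates),
                      p_level = levels, genotype = genos,
                      stringsAsFactors = FALSE)[, c(3, 2, 1)]
  n <- nrow(grid)
  e <- latent[grid$genotype]
  b <- cfg$genotype_effect[grid$p_level]
  gm <- gamma[cbind(match(grid$genotype, genos), match(grid$p_level, levels))]
  shoot <- cfg$shoot_dw_mean[grid$p_level] *
    exp(b * e + gm + stats::rnorm(n, 0, sdlog))
  root <- shoot * cfg$root_shoot_ratio[grid$p_level] *
    exp(stats::rnorm(n, 0, sdlog / 2))
  frac <- cfg$pconc_frac[grid$p_level] *
    exp(cfg$conc_effect * e + stats::rnorm(n, 0, sdlog / 2))
  uptake <- (shoot + root) * frac
  tibble::tibble(genotype = grid$genotype, p_level = grid$p_level,
                 replicate = grid$replicate,
                 shoot_dw = unname(shoot), root_dw = unname(root),
                 plant_p_concentration = unname(frac * cfg$conc_unit_factor),
                 p_uptake = unname(uptake),
                 height = NA_real_, culms = NA_real_)
}

trial_design_from_config <- function(cfg) {
  trial_design(genotypes = sim_genotype_labels(cfg$n_genotypes),
               p_levels = c("P+", "P-"), p_applied = cfg$p_applied,
               replicates_per_cell = cfg$replicates,
               platform_label = cfg$platform_label)
}

#' Simulate a factorial harvest trial with known ground truth
#'
#' Draws a latent efficiency per genotype and a genotype x level
#' interaction, then generates per-tube harvest records under a log-scale
#' linear model with multiplicative residual noise. Tissue P concentration
#' is lower under deficiency and P uptake is consistent with
#' (shoot + root) x concentration by construction. The ground-truth metric
#' table is obtained by aggregating the noise-free expectations through
#' [compute_metric_table()] itself, so every downstream stage can be scored
#' without re-deriving formulas.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `records` (tibble,
#'   `n_genotypes * 2 * replicates` rows), `truth` (noise-free
#'   [metric_table()]), `latent` (named efficiency vector), `design` and
#'   `config`.
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  genos <- sim_genotype_labels(cfg$n_genotypes)
  latent <- stats::setNames(stats::rnorm(cfg$n_genotypes), genos)
  gamma <- matrix(stats::rnorm(2L * cfg$n_genotypes, 0, cfg$interaction_sd),
                  ncol = 2L, dimnames = list(genos, c("P+", "P-")))
  design <- trial_design_from_config(cfg)
  records <- generate_records(cfg, latent, gamma, noisy = TRUE)
  truth_cfg <- cfg; truth_cfg$replicates <- 1L
  truth_records <- generate_records(truth_cfg, latent, gamma, noisy = FALSE)
  truth_design <- design; truth_design$replicates_per_cell <- 1L
  truth <- suppressWarnings(compute_metric_table(truth_records, truth_design))
  list(records = records, truth = truth, latent = latent,
       design = design, config = cfg)
}

#' Simulate two platforms measuring the same genotype panel
#'
#' Latent genotype efficiencies for the two platforms are drawn from a
#' bivariate standard normal with correlation `rho_true`; each platform then
#' maps its latent vector to a noise-free genotype-level metric table under
#' platform-specific baselines (the second platform grows larger plants
#' with higher tissue P, mimicking a longer soil trial). Min-max
#' normalization inside the P indicator removes platform scale and offset,
#' so the recovered indicator correlation estimates `rho_true`.
#'
#' @param cfg A [simulation_config()]; `rho_true` and `seed` are used, and
#'   the platform baselines derive from the other fields.
#' @return A list with `table_a`, `table_b` (noise-free [metric_table()]s),
#'   `latent_a`, `latent_b` and `rho_true`.
#' @export
simulate_paired_platforms <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  rho <- cfg$rho_true
  genos <- sim_genotype_labels(cfg$n_genotypes)
  e_a <- stats::rnorm(cfg$n_genotypes)
  e_b <- rho * e_a + sqrt(1 - rho^2) * stats::rnorm(cfg$n_genotypes)
  latent_a <- stats::setNames(e_a, genos)
  latent_b <- stats::setNames(e_b, genos)
  gamma0 <- matrix(0, cfg$n_genotypes, 2L,
                   dimnames = list(genos, c("P+", "P-")))

  cfg_a <- cfg; cfg_a$replicates <- 1L; cfg_a$platform_label <- "platform_A"
  cfg_b <- cfg; cfg_b$replicates <- 1L; cfg_b$platform_label <- "platform_B"
  # platform distortions: larger plants, higher tissue P, smaller P supply
  # contrast on the second platform
  cfg_b$shoot_dw_mean <- cfg$shoot_dw_mean * c("P+" = 2.2, "P-" = 1.4)
  cfg_b$pconc_frac <- cfg$pconc_frac * 1.8
  cfg_b$root_shoot_ratio <- cfg$root_shoot_ratio * 1.1

  tab_a <- suppressWarnings(compute_metric_table(
    generate_records(cfg_a, latent_a, gamma0, noisy = FALSE),
    trial_design_from_config(cfg_a)))
  tab_b <- suppressWarnings(compute_metric_table(
    generate_records(cfg_b, latent_b, gamma0, noisy = FALSE),
    trial_design_from_config(cfg_b)))
  list(table_a = tab_a, table_b = tab_b,
       latent_a = latent_a, latent_b = latent_b, rho_true = rho)
}

#' Simulate longitudinal root-area growth curves
#'
#' Per-tube logistic growth `area(t) = A / (1 + exp(-(t - t0)/s))` with
#' genotype-specific asymptote and midpoint, a treatment multiplier on the
#' asymptote under P deficiency, a multiplicative per-tube random
#' intercept, and additive Gaussian measurement noise.
#'
#' @param n_genotypes,replicates Panel size (tubes per genotype x level).
#' @param times Strictly increasing observation days (>= 4 points).
#' @param asymptote_mean Mean asymptotic projected area (area units).
#' @param asymptote_cv CV of the genotype asymptote.
#' @param midpoint_mean,midpoint_sd Inflection day distribution.
#' @param rate Logistic time scale (days).
#' @param treatment_multiplier Asymptote multiplier under the low-P level.
#' @param tube_sd Log-scale SD of the per-tube random intercept.
#' @param noise_sd Additive measurement noise SD (area units).
#' @param seed Integer seed.
#' @return A list with `series` (tibble: tube_id, genotype, p_level, time,
#'   area) and `truth` (per genotype x level logistic parameters).
#' @export
simulate_growth_series <- function(n_genotypes = 4L, replicates = 4L,
                                   times = seq(4, 96, by = 4),
                                   asymptote_mean = 120, asymptote_cv = 0.2,
                                   midpoint_mean = 45, midpoint_sd = 5,
                                   rate = 10, treatment_multiplier = 0.85,
                                   tube_sd = 0.05, noise_sd = 1, seed) {
  if (missing(seed)) stop("an integer `seed` is mandatory")
  if (length(times) < 4L) stop("need at least four time points")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  set.seed(as.integer(seed))
  genos <- sim_genotype_labels(n_genotypes)
  truth <- expand.grid(genotype = genos, p_level = c("P+", "P-"),
                       stringsAsFactors = FALSE)
  a_geno <- stats::setNames(
    asymptote_mean * exp(stats::rnorm(n_genotypes, 0, cv_to_sdlog(asymptote_cv))),
    genos)
  t0_geno <- stats::setNames(stats::rnorm(n_genotypes, midpoint_mean, midpoint_sd),
                             genos)
  truth$asymptote <- a_geno[truth$genotype] *
    ifelse(truth$p_level == "P-", treatment_multiplier, 1)
  truth$midpoint <- t0_geno[truth$genotype]
  truth$rate <- rate
  rows <- vector("list", nrow(truth) * replicates)
  k <- 0L
  for (i in seq_len(nrow(truth))) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      tube_eff <- exp(stats::rnorm(1, 0, tube_sd))
      mu <- truth$asymptote[i] * tube_eff /
        (1 + exp(-(times - truth$midpoint[i]) / rate))
      area <- pmax(mu + stats::rnorm(length(times), 0, noise_sd), 0)
      rows[[k]] <- tibble::tibble(
        tube_id = sprintf("%s_%s_t%02d", truth$genotype[i], truth$p_level[i], r),
        genotype = truth$genotype[i], p_level = truth$p_level[i],
        time = times, area = area)
    }
  }
  list(series = dplyr::bind_rows(rows), truth = tibble::as_tibble(truth))
}

#' Render a synthetic root scene with known ground truth
#'
#' Draws a downward-growing random-walk branching skeleton, dilates it to
#' the requested stroke width, composes a grayscale image (roots darker
#' than the background) with additive Gaussian noise, and cuts the panorama
#' into six horizontally overlapping views with known offsets — everything
#' the imaging chain consumes, plus the true mask and area to score it.
#'
#' @param width,height Panorama size in pixels.
#' @param n_branches Number of root branches (0 gives a blank scene).
#' @param stroke_width Root stroke width in pixels (>= 1).
#' @param noise_sigma Additive Gaussian noise SD.
#' @param seed Integer seed.
#' @param n_views Number of views to cut (default 6).
#' @param overlap Horizontal overlap between consecutive views in pixels.
#' @return A list with `image`, `mask`, `area_px`, `stack` (a
#'   [view_stack()]), `offsets` (true 0-based view offsets) and `overlap`.
#' @export
render_root_scene <- function(width = 360L, height = 240L, n_branches = 8L,
                              stroke_width = 3L, noise_sigma = 0.03, seed,
                              n_views = 6L, overlap = 24L) {
  if (missing(seed)) stop("an integer `seed` is mandatory")
  if (stroke_width < 1L) stop("`stroke_width` must be >= 1")
  set.seed(as.integer(seed))
  step <- (width - overlap) %/% n_views
  width <- step * n_views + overlap  # exact view tiling
  mask <- matrix(FALSE, height, width)
  rad <- (stroke_width - 1L) %/% 2L
  stamp <- function(r, c) {
    rr <- max(1L, r - rad):min(height, r + rad)
    cc <- max(1L, c - rad):min(width, c + rad)
    mask[rr, cc] <<- TRUE
  }
  if (n_branches > 0L) {
    # one connected system: a primary axis from the top, laterals branching
    # off points already on the skeleton (as roots do from the seed)
    skeleton <- matrix(integer(), ncol = 2L)
    grow <- function(r, c, len, drift) {
      end_row <- min(height, r + len)
      while (r < end_row) {
        r <- r + 1L
        # lateral step clamped to one pixel per row so the dilated stroke
        # stays 8-connected (real roots do not teleport sideways)
        c <- c + max(-1L, min(1L, round(stats::rnorm(1, drift, 1.0))))
        c <- min(max(c, 1L + rad), width - rad)
        stamp(r, c)
        skeleton <<- rbind(skeleton, c(r, c))
      }
    }
    grow(1L, round(stats::runif(1, width * 0.35, width * 0.65)),
         len = round(0.95 * height), drift = 0)
    for (b in seq_len(n_branches - 1L)) {
      origin <- skeleton[sample.int(nrow(skeleton), 1L), ]
      grow(origin[1L], origin[2L],
           len = round(stats::runif(1, 0.2, 0.6) * height),
           drift = stats::rnorm(1, 0, 0.6))
    }
  }
  image <- 0.85 - 0.55 * mask + stats::rnorm(length(mask), 0, noise_sigma)
  image <- matrix(pmin(pmax(image, 0), 1), height, width)
  offsets <- (seq_len(n_views) - 1L) * step
  views <- lapply(offsets, function(o) image[, (o + 1L):(o + step + overlap)])
  list(image = image, mask = mask, area_px = sum(mask),
       stack = view_stack(views), offsets = offsets, overlap = overlap)
}
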