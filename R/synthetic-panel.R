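# Synthetic screen-design emulation: panel configuration, effect parameters
# and the endpoint-measurement generator. All randomness is seeded through
# the config so identical configurations give byte-identical tables.

#' Growth-effect parameters for the synthetic generator
#'
#' Parameterises how the two tolerance classes respond to B deficiency, and
#' the logistic shoot-growth model used for image-series simulation. Ratios
#' are deficient/adequate (B0/B1) multipliers on the class mean: a
#' B-efficient accession keeps most of its biomass under deficiency (ratio
#' near 1), a B-inefficient one arrests at the cotyledon stage (ratio near
#' 0; endpoint dry weight in the screen dropped by more than 90%).
#'
#' @param baseline_DW_mg mean shoot dry weight (mg) under adequate B.
#' @param baseline_L1_mm mean first-leaf (L1) length (mm) under adequate B.
#' @param baseline_hypocotyl_mm mean hypocotyl length (mm) under adequate B.
#' @param deficiency_DW_ratio_efficient,deficiency_DW_ratio_inefficient
#'   B0/B1 dry-weight ratio for each class, in (0, 1.5].
#' @param deficiency_L1_ratio_efficient,deficiency_L1_ratio_inefficient
#'   B0/B1 L1-length ratio for each class, in (0, 1.5].
#' @param surplus_ratio B2/B1 multiplier applied to all traits (surplus B is
#'   non-toxic at the monitored stages; default 1).
#' @param ratio_jitter_sd log-scale SD of per-accession jitter on the true
#'   deficiency ratios around the class value (default 0: every accession of
#'   a class shares the class ratios exactly). Jittered ratios are truncated
#'   to (0, 1.5].
#' @param arrest_day_inefficient day after sowing (DAS) at which inefficient
#'   plants under deficiency freeze their projected area (default 9).
#' @param logistic_rate per-day rate of the logistic area trajectory.
#' @param logistic_capacity asymptotic projected area (px).
#' @param logistic_midpoint_das DAS of the logistic inflection point.
#' @param dry_matter_fraction DW/FW fraction used to derive fresh weight and
#'   water content from dry weight.
#' @return an object of class `growth_effect_params` (a validated list).
#' @export
#' @examples
#' growth_effect_params(deficiency_DW_ratio_efficient = 0.95)
growth_effect_params <- function(baseline_DW_mg = 150,
                                 baseline_L1_mm = 60,
                                 baseline_hypocotyl_mm = 25,
                                 deficiency_DW_ratio_efficient = 0.90,
                                 deficiency_DW_ratio_inefficient = 0.05,
                                 deficiency_L1_ratio_efficient = 0.95,
                                 deficiency_L1_ratio_inefficient = 0.08,
                                 surplus_ratio = 1.0,
                                 ratio_jitter_sd = 0,
                                 arrest_day_inefficient = 9L,
                                 logistic_rate = 0.35,
                                 logistic_capacity = 5e4,
                                 logistic_midpoint_das = 10,
                                 dry_matter_fraction = 0.1) {
  check_positive(baseline_DW_mg, "baseline_DW_mg")
  check_positive(baseline_L1_mm, "baseline_L1_mm")
  check_positive(baseline_hypocotyl_mm, "baseline_hypocotyl_mm")
  for (nm in c("deficiency_DW_ratio_efficient", "deficiency_DW_ratio_inefficient",
               "deficiency_L1_ratio_efficient", "deficiency_L1_ratio_inefficient",
               "surplus_ratio")) {
    val <- get(nm)
    if (length(val) != 1L || !is.finite(val) || val <= 0 || val > 1.5) {
      abort_boreff(sprintf("`%s` must be in (0, 1.5]", nm),
                   "boreff_config_error")
    }
  }
  check_fraction(ratio_jitter_sd, "ratio_jitter_sd", 0, Inf)
  check_count(arrest_day_inefficient, "arrest_day_inefficient", min = 1L)
  check_positive(logistic_rate, "logistic_rate")
  check_positive(logistic_capacity, "logistic_capacity")
  check_positive(logistic_midpoint_das, "logistic_midpoint_das")
  check_fraction(dry_matter_fraction, "dry_matter_fraction", 0, 1)
  structure(
    list(
      baseline_DW_mg = baseline_DW_mg,
      baseline_L1_mm = baseline_L1_mm,
      baseline_hypocotyl_mm = baseline_hypocotyl_mm,
      deficiency_DW_ratio_efficient = deficiency_DW_ratio_efficient,
      deficiency_DW_ratio_inefficient = deficiency_DW_ratio_inefficient,
      deficiency_L1_ratio_efficient = deficiency_L1_ratio_efficient,
      deficiency_L1_ratio_inefficient = deficiency_L1_ratio_inefficient,
      surplus_ratio = surplus_ratio,
      ratio_jitter_sd = ratio_jitter_sd,
      arrest_day_inefficient = as.integer(arrest_day_inefficient),
      logistic_rate = logistic_rate,
      logistic_capacity = logistic_capacity,
      logistic_midpoint_das = logistic_midpoint_das,
      dry_matter_fraction = dry_matter_fraction
    ),
    class = "growth_effect_params"
  )
}

#' Panel configuration for the synthetic screen
#'
#' Describes the design of a synthetic accession panel mirroring the real
#' screen: 234 spring-type and 356 winter-type accessions, three soil-boron
#' treatments (B0 deficient, B1 adequate, B2 surplus), at least 10-12
#' replicate plants per accession and condition, and a rare B-efficient
#' class (3 of 590 in the screen).
#'
#' @param n_spring,n_winter number of spring-/winter-type accessions.
#' @param treatments treatment labels; `"B0"` is deficient and `"B1"` the
#'   adequate reference; any subset of `c("B0","B1","B2")`.
#' @param replicates_per_condition plants per accession x treatment
#'   (default 12).
#' @param efficient_fraction probability that an accession is B-efficient
#'   (default 3/590, the rarity observed in the screen). Winter-type
#'   accessions are always inefficient, as in the screen.
#' @param effect a [growth_effect_params()] object.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   replicate noise on weight traits (default 0.15). Linear traits (L1,
#'   hypocotyl) use `noise_cv / 3`: if mass scales with the cube of linear
#'   size, the CV of a length is about a third the CV of a weight.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return an object of class `panel_config`.
#' @export
#' @examples
#' cfg <- panel_config(n_spring = 5, n_winter = 5, seed = 1)
panel_config <- function(n_spring = 234L,
                         n_winter = 356L,
                         treatments = c("B0", "B1", "B2"),
                         replicates_per_condition = 12L,
                         efficient_fraction = 3 / 590,
                         effect = growth_effect_params(),
                         noise_cv = 0.15,
                         seed) {
  check_count(n_spring, "n_spring")
  check_count(n_winter, "n_winter")
  if (n_spring + n_winter < 1L) {
    abort_boreff("panel must contain at least one accession",
                 "boreff_config_error")
  }
  if (length(treatments) < 1L || !all(treatments %in% c("B0", "B1", "B2"))) {
    abort_boreff('`treatments` must be a subset of c("B0", "B1", "B2")',
                 "boreff_config_error")
  }
  check_count(replicates_per_condition, "replicates_per_condition", min = 1L)
  check_fraction(efficient_fraction, "efficient_fraction")
  if (!inherits(effect, "growth_effect_params")) {
    abort_boreff("`effect` must be a growth_effect_params object",
                 "boreff_config_error")
  }
  check_fraction(noise_cv, "noise_cv", 0, Inf)
  if (missing(seed)) {
    abort_boreff("`seed` is mandatory", "boreff_config_error")
  }
  check_count(seed, "seed")
  structure(
    list(
      n_spring = as.integer(n_spring),
      n_winter = as.integer(n_winter),
      treatments = unique(treatments),
      replicates_per_condition = as.integer(replicates_per_condition),
      efficient_fraction = efficient_fraction,
      effect = effect,
      noise_cv = noise_cv,
      seed = as.integer(seed)
    ),
    class = "panel_config"
  )
}

# class- and treatment-dependent true trait means for one accession
.true_means <- function(trait_baseline, ratio_deficient, surplus_ratio,
                        treatment) {
  switch(treatment,
    B0 = trait_baseline * ratio_deficient,
    B1 = trait_baseline,
    B2 = trait_baseline * surplus_ratio,
    abort_boreff(sprintf("unknown treatment label '%s'", treatment),
                 "boreff_config_error")
  )
}

#' Generate a synthetic accession panel with endpoint measurements
#'
#' Emulates the endpoint stage of the screen: each accession is assigned a
#' hidden tolerance class (B-efficient with probability
#' `efficient_fraction`; winter types are always inefficient), and
#' `replicates_per_condition` plants per accession x treatment are drawn
#' with multiplicative lognormal noise around class- and
#' treatment-dependent true means. Fresh weight and water content are
#' derived from dry weight through the dry-matter fraction.
#'
#' @param config a [panel_config()] object.
#' @return a list with three tibbles:
#' \describe{
#'   \item{manifest}{one row per accession: `accession_id`, `type_label`
#'     (spring/winter), hidden `true_class`.}
#'   \item{measurements}{one row per plant: `accession_id`, `type_label`,
#'     `treatment`, `replicate`, `DW_mg`, `FW_mg`, `L1_mm`, `hypocotyl_mm`,
#'     `water_content_pct`.}
#'   \item{ground_truth}{one row per accession: true deficiency ratios and
#'     the true BEI (`true_dw_ratio * true_l1_ratio`).}
#' }
#' @export
#' @examples
#' panel <- generate_panel(panel_config(n_spring = 3, n_winter = 2, seed = 1))
#' nrow(panel$manifest)
generate_panel <- function(config) {
  if (!inherits(config, "panel_config")) {
    abort_boreff("`config` must be a panel_config object",
                 "boreff_config_error")
  }
  set.seed(config$seed)
  eff <- config$effect
  n_acc <- config$n_spring + config$n_winter
  acc_id <- sprintf("ACC%04d", seq_len(n_acc))
  type_label <- c(rep("spring", config$n_spring),
                  rep("winter", config$n_winter))
  is_eff <- runif(n_acc) < config$efficient_fraction
  is_eff[type_label == "winter"] <- FALSE  # no efficient winter type found
  true_class <- ifelse(is_eff, "efficient", "inefficient")

  jitter_ratio <- function(base) {
    if (eff$ratio_jitter_sd == 0) return(rep(base, n_acc))
    r <- base * exp(rnorm(n_acc, 0, eff$ratio_jitter_sd))
    pmin(pmax(r, 1e-4), 1.5)
  }
  true_dw_ratio <- ifelse(is_eff,
                          jitter_ratio(eff$deficiency_DW_ratio_efficient),
                          jitter_ratio(eff$deficiency_DW_ratio_inefficient))
  true_l1_ratio <- ifelse(is_eff,
                          jitter_ratio(eff$deficiency_L1_ratio_efficient),
                          jitter_ratio(eff$deficiency_L1_ratio_inefficient))

  manifest <- tibble::tibble(
    accession_id = acc_id,
    type_label = type_label,
    true_class = true_class
  )
  ground_truth <- tibble::tibble(
    accession_id = acc_id,
    true_class = true_class,
    true_dw_ratio = true_dw_ratio,
    true_l1_ratio = true_l1_ratio,
    true_bei = true_dw_ratio * true_l1_ratio
  )

  reps <- config$replicates_per_condition
  grid <- tidyr::expand_grid(
    accession_id = acc_id,
    treatment = config$treatments,
    replicate = seq_len(reps)
  )
  idx <- match(grid$accession_id, acc_id)
  dw_ratio_t <- ifelse(grid$treatment == "B0", true_dw_ratio[idx],
                       ifelse(grid$treatment == "B2", eff$surplus_ratio, 1))
  l1_ratio_t <- ifelse(grid$treatment == "B0", true_l1_ratio[idx],
                       ifelse(grid$treatment == "B2", eff$surplus_ratio, 1))
  n_row <- nrow(grid)
  cv_len <- config$noise_cv / 3
  dw <- eff$baseline_DW_mg * dw_ratio_t * lnorm_noise(n_row, config$noise_cv)
  l1 <- eff$baseline_L1_mm * l1_ratio_t * lnorm_noise(n_row, cv_len)
  hyp <- eff$baseline_hypocotyl_mm * l1_ratio_t * lnorm_noise(n_row, cv_len)
  fw <- dw / eff$dry_matter_fraction
  measurements <- tibble::tibble(
    accession_id = grid$accession_id,
    type_label = manifest$type_label[idx],
    treatment = grid$treatment,
    replicate = grid$replicate,
    DW_mg = dw,
    FW_mg = fw,
    L1_mm = l1,
    hypocotyl_mm = hyp,
    water_content_pct = 100 * (fw - dw) / fw
  )
  list(manifest = manifest, measurements = measurements,
       ground_truth = ground_truth)
}
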