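# Synthetic time-series generators: projected-area growth trajectories and
# plate-assay root-depth series.

#' Simulate a projected-area growth series for one plant
#'
#' Area follows a logistic trajectory
#' \eqn{A(t) = K / (1 + e^{-r (t - t_0)})}. For a B-inefficient plant under
#' the deficient treatment (`"B0"`) the area is frozen at its
#' `arrest_day_inefficient` value from that day onward, emulating the
#' arrested shoot-apical-meristem phenotype (growth stops, tissue does not
#' senesce within the imaging window). An efficient plant under deficiency
#' is scaled by the class deficiency dry-weight ratio. Border length is a
#' monotone function of area (`border_scale * sqrt(area)`), as for a shape
#' growing roughly isometrically. Measurement noise is multiplicative
#' lognormal per observation; it models imaging repeatability of a pixel
#' count and is therefore much smaller than biological replicate noise.
#'
#' @param class `"efficient"` or `"inefficient"`.
#' @param treatment `"B0"` (deficient), `"B1"` (adequate) or `"B2"`.
#' @param params a [growth_effect_params()] object.
#' @param seed integer RNG seed.
#' @param days DAS vector (default `4:13`, the span used for the RGR
#'   windows); must cover the arrest day for arrest to be representable.
#' @param area_noise_cv imaging measurement CV (default 0.03).
#' @param border_scale border-length coefficient (px per sqrt(px)).
#' @param plant_id,accession_id identifiers carried into the output.
#' @return a tibble of class `growth_series` with columns `plant_id`,
#'   `accession_id`, `treatment`, `das`, `area`, `border_length`, plus
#'   attributes `true_arrested` (logical) and `true_arrest_das`.
#' @export
#' @examples
#' s <- simulate_growth_series("inefficient", "B0", growth_effect_params(),
#'                             seed = 1, area_noise_cv = 0)
#' s$area[s$das == 12] == s$area[s$das == 9]
simulate_growth_series <- function(class = c("efficient", "inefficient"),
                                   treatment = c("B0", "B1", "B2"),
                                   params = growth_effect_params(),
                                   seed,
                                   days = 4:13,
                                   area_noise_cv = 0.03,
                                   border_scale = 6,
                                   plant_id = "plant_1",
                                   accession_id = "ACC0001") {
  class <- match.arg(class)
  treatment <- match.arg(treatment)
  if (!inherits(params, "growth_effect_params")) {
    abort_boreff("`params` must be a growth_effect_params object",
                 "boreff_config_error")
  }
  check_count(seed, "seed")
  days <- sort(unique(as.integer(days)))
  if (length(days) < 2L) {
    abort_boreff("`days` must contain at least two DAS values",
                 "boreff_config_error")
  }
  arrested <- class == "inefficient" && treatment == "B0"
  if (arrested &&
      (params$arrest_day_inefficient < min(days) ||
       params$arrest_day_inefficient > max(days))) {
    abort_boreff("arrest_day_inefficient lies outside the simulated DAS span",
                 "boreff_config_error")
  }
  set.seed(seed)
  scale <- switch(treatment,
    B0 = if (class == "efficient") params$deficiency_DW_ratio_efficient else 1,
    B1 = 1,
    B2 = params$surplus_ratio
  )
  logistic <- function(t) {
    params$logistic_capacity /
      (1 + exp(-params$logistic_rate * (t - params$logistic_midpoint_das)))
  }
  area_true <- scale * logistic(days)
  true_arrest_das <- NA_integer_
  if (arrested) {
    true_arrest_das <- params$arrest_day_inefficient
    frozen <- days >= true_arrest_das
    area_true[frozen] <- scale * logistic(true_arrest_das)
  }
  area <- area_true * lnorm_noise(length(days), area_noise_cv)
  border <- border_scale * sqrt(area_true) *
    lnorm_noise(length(days), area_noise_cv)
  out <- tibble::tibble(
    plant_id = plant_id,
    accession_id = accession_id,
    treatment = treatment,
    das = days,
    area = area,
    border_length = border
  )
  attr(out, "true_arrested") <- arrested
  attr(out, "true_arrest_das") <- true_arrest_das
  class(out) <- c("growth_series", class(out))
  out
}

#' Simulate a root-depth series for one plate-assay seedling
#'
#' Emulates the root cessation assay: the primary-root depth is marked
#' directly after transfer (day 0) and every 24 h for `n_days` days. Under
#' the B-sufficient condition the daily gain is approximately constant.
#' Under deficiency an inefficient seedling decelerates: its gains ramp
#' linearly from `initial_gain_cm` down to zero by day `ramp_days`
#' (deceleration within a day, complete cessation after three more, as seen
#' across nearly all accessions). An efficient seedling keeps a nonnegative
#' gain trend (`efficient_trend`). Gains get multiplicative lognormal
#' noise, so depth stays nondecreasing by construction.
#'
#' @param class `"efficient"` or `"inefficient"`.
#' @param condition `"sufficient"` (5 uM B) or `"deficient"` (0.01 uM B).
#' @param seed integer RNG seed.
#' @param n_days number of daily marks after transfer (default 5).
#' @param initial_gain_cm gain in the first day after transfer (cm).
#' @param efficient_trend gain slope (cm/day per day) for efficient
#'   seedlings under deficiency (default +0.05, the positive acceleration
#'   seen in the tolerant accessions).
#' @param ramp_days day offset by which an inefficient seedling's gain
#'   reaches zero under deficiency (default 4).
#' @param gain_noise_cv measurement CV of each daily gain (default 0.10).
#' @param initial_depth_cm depth of the mark at transfer (cm).
#' @param seedling_id,accession_id identifiers carried into the output.
#' @return a tibble of class `root_depth_series` with columns
#'   `seedling_id`, `accession_id`, `condition`, `day`, `depth_cm`, plus
#'   attribute `true_gain_trend` (cm/day per day).
#' @export
#' @examples
#' s <- simulate_root_depth_series("inefficient", "deficient", seed = 1,
#'                                 gain_noise_cv = 0)
#' diff(s$depth_cm)
simulate_root_depth_series <- function(class = c("efficient", "inefficient"),
                                       condition = c("sufficient", "deficient"),
                                       seed,
                                       n_days = 5L,
                                       initial_gain_cm = 2,
                                       efficient_trend = 0.05,
                                       ramp_days = 4L,
                                       gain_noise_cv = 0.10,
                                       initial_depth_cm = 4,
                                       seedling_id = "seedling_1",
                                       accession_id = "ACC0001") {
  class <- match.arg(class)
  condition <- match.arg(condition)
  check_count(seed, "seed")
  check_count(n_days, "n_days", min = 4L)
  check_positive(initial_gain_cm, "initial_gain_cm")
  check_count(ramp_days, "ramp_days", min = 1L)
  check_fraction(gain_noise_cv, "gain_noise_cv", 0, Inf)
  set.seed(seed)
  day_offsets <- seq_len(n_days)  # gain of day k covers (k-1, k]
  if (condition == "sufficient") {
    true_trend <- 0
    gains <- rep(initial_gain_cm, n_days)
  } else if (class == "inefficient") {
    true_trend <- -initial_gain_cm / ramp_days
    gains <- pmax(initial_gain_cm + true_trend * (day_offsets - 1), 0)
  } else {
    true_trend <- efficient_trend
    gains <- pmax(initial_gain_cm + true_trend * (day_offsets - 1), 0)
  }
  gains <- gains * lnorm_noise(n_days, gain_noise_cv)
  out <- tibble::tibble(
    seedling_id = seedling_id,
    accession_id = accession_id,
    condition = condition,
    day = c(0L, day_offsets),
    depth_cm = initial_depth_cm + cumsum(c(0, gains))
  )
  attr(out, "true_gain_trend") <- true_trend
  class(out) <- c("root_depth_series", class(out))
  out
}

# arclength of an (n x 2) polyline matrix
polyline_length <- function(xy) {
  if (!is.matrix(xy) || ncol(xy) != 2L || nrow(xy) < 2L ||
      !all(is.finite(xy))) {
    abort_boreff("polyline must be a finite (n >= 2) x 2 matrix",
                 "boreff_data_error")
  }
  sum(sqrt(rowSums(diff(xy)^2)))
}

#' Simulate a traced root system with exact arclengths
#'
#' Builds a wiggly primary-root polyline of exact arclength
#' `pr_length_cm` (random small heading perturbations around straight-down
#' growth, rescaled to the target length) and attaches `n_laterals`
#' first-order lateral polylines, each of exact arclength
#' `lateral_length_cm`, at distinct points along the primary root.
#'
#' @param n_laterals number of first-order laterals (>= 0).
#' @param pr_length_cm primary-root arclength (cm, > 0).
#' @param lateral_length_cm arclength of each lateral (cm, > 0).
#' @param seed integer RNG seed.
#' @param segments_per_cm polyline sampling density.
#' @return an object of class `root_trace`: a list with `primary`
#'   (matrix of x, y in cm), `laterals` (list of matrices), and recorded
#'   ground truth `true_pr_length_cm`, `true_total_lateral_cm`.
#' @export
#' @examples
#' tr <- simulate_root_trace(5, 10, 2, seed = 1)
#' length(tr$laterals)
simulate_root_trace <- function(n_laterals, pr_length_cm, lateral_length_cm,
                                seed, segments_per_cm = 4) {
  check_count(n_laterals, "n_laterals")
  check_positive(pr_length_cm, "pr_length_cm")
  if (n_laterals > 0) check_positive(lateral_length_cm, "lateral_length_cm")
  check_count(seed, "seed")
  set.seed(seed)

  wiggly <- function(total_len, origin, base_heading) {
    n_seg <- max(2L, ceiling(total_len * segments_per_cm))
    headings <- base_heading + cumsum(rnorm(n_seg, 0, 0.08))
    steps <- cbind(cos(headings), sin(headings))  # unit steps
    path <- rbind(c(0, 0), cbind(cumsum(steps[, 1]), cumsum(steps[, 2])))
    # unit-speed polyline has arclength n_seg; rescale, then translate
    sweep(path * (total_len / n_seg), 2, origin, `+`)
  }

  primary <- wiggly(pr_length_cm, c(0, 0), -pi / 2)  # grows downward (-y)
  laterals <- list()
  if (n_laterals > 0) {
    # distinct attachment vertices, excluding the tip and base
    n_vert <- nrow(primary)
    pool <- seq(2L, n_vert - 1L)
    if (length(pool) < n_laterals) {
      abort_boreff("primary root too short for that many distinct laterals",
                   "boreff_config_error")
    }
    at <- sort(sample(pool, n_laterals))
    side <- rep_len(c(1, -1), n_laterals)
    laterals <- lapply(seq_len(n_laterals), function(i) {
      wiggly(lateral_length_cm, primary[at[i], ],
             base_heading = side[i] * pi / 12 + (side[i] - 1) / 2 * pi)
    })
  }
  structure(
    list(
      primary = primary,
      laterals = laterals,
      true_pr_length_cm = pr_length_cm,
      true_total_lateral_cm = n_laterals *
        (if (n_laterals > 0) lateral_length_cm else 0)
    ),
    class = "root_trace"
  )
}
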