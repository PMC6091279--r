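# Root cessation assay analytics: daily primary-root depth gain, the slope
# of the gain-vs-time ("acceleration") curve, and the cessation call.
#
# The gain curve is the daily primary-root depth gain plotted against day
# offset after transfer; its ordinary-least-squares slope is the root
# growth acceleration. A negative slope under B deficiency is root
# cessation; a nonnegative slope is the non-cessation response seen only
# in B-efficient accessions.

#' Daily primary-root depth gain
#'
#' First differences of the daily depth marks, in cm/day. Depth marks must
#' be nondecreasing (roots do not retract); a decreasing series is a data
#' integrity error naming the seedling.
#'
#' @param series data frame with columns `day` and `depth_cm` for one
#'   seedling (e.g. from [simulate_root_depth_series()]); a `seedling_id`
#'   column is used in error messages when present.
#' @return tibble with `day` (offset of the gained day) and `gain_cm`.
#' @export
#' @examples
#' daily_depth_gain(data.frame(day = 0:3, depth_cm = c(0, 1, 2, 3)))
daily_depth_gain <- function(series) {
  stopifnot(all(c("day", "depth_cm") %in% names(series)))
  ord <- order(series$day)
  day <- series$day[ord]
  depth <- series$depth_cm[ord]
  if (length(depth) < 2L) {
    abort_boreff("need at least two depth marks to compute a gain",
                 "boreff_data_error")
  }
  gains <- diff(depth)
  if (any(gains < 0)) {
    id <- if ("seedling_id" %in% names(series)) series$seedling_id[1] else
      "unknown seedling"
    abort_boreff(
      sprintf("decreasing root depth for %s: depth marks must be nondecreasing",
              id),
      "boreff_data_error"
    )
  }
  tibble::tibble(day = day[-1], gain_cm = gains)
}

# closed-form OLS slope of y on x
.ols_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Slope coefficient of the root-gain curve
#'
#' Fits the OLS slope of daily depth gain against day offset for each
#' seedling, then (default pooling `"per_seedling"`) averages the slopes
#' over seedlings — so unbalanced seedling counts cannot bias an
#' accession's coefficient. With pooling `"pooled"` a single regression is
#' fitted to all gain points of the accession x condition. Seedlings with
#' fewer than 3 gains are excluded and reported; if all are excluded, an
#' error is raised.
#'
#' @param depth_tbl long table with columns `seedling_id`, `day`,
#'   `depth_cm` for one accession x condition (extra columns
#'   `accession_id`, `condition` are carried through when constant).
#' @param pooling `"per_seedling"` (default) or `"pooled"`.
#' @return a list of class `slope_result`: `accession_id`, `condition`,
#'   `slope_coefficient` (cm/day per day), `slope_sd`, `n_seedlings`,
#'   `mean_gain_per_day` (tibble of mean gain per day offset),
#'   `cessation_flag` (`slope_coefficient < 0`), `excluded_seedlings`.
#' @export
#' @examples
#' d <- simulate_root_depth_series("inefficient", "deficient", seed = 1,
#'                                 gain_noise_cv = 0)
#' gain_slope_coefficient(d)$slope_coefficient  # -0.5
gain_slope_coefficient <- function(depth_tbl,
                                   pooling = c("per_seedling", "pooled")) {
  pooling <- match.arg(pooling)
  stopifnot(all(c("seedling_id", "day", "depth_cm") %in% names(depth_tbl)))
  ids <- unique(depth_tbl$seedling_id)
  gains <- list()
  excluded <- character()
  for (id in ids) {
    g <- daily_depth_gain(depth_tbl[depth_tbl$seedling_id == id, ])
    if (nrow(g) < 3L) {
      excluded <- c(excluded, id)
    } else {
      g$seedling_id <- id
      gains[[id]] <- g
    }
  }
  if (length(gains) == 0L) {
    abort_boreff("all seedlings excluded (fewer than 3 gains each)",
                 "boreff_data_error")
  }
  gains <- dplyr::bind_rows(gains)
  if (pooling == "per_seedling") {
    slopes <- vapply(split(gains, gains$seedling_id),
                     function(g) .ols_slope(g$day, g$gain_cm), numeric(1))
    slope <- mean(slopes)
    slope_sd <- if (length(slopes) > 1) sd(slopes) else NA_real_
  } else {
    slope <- .ols_slope(gains$day, gains$gain_cm)
    slope_sd <- NA_real_
  }
  mean_gain <- gains |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(mean_gain_cm = mean(.data$gain_cm), .groups = "drop")
  get_const <- function(col) {
    if (col %in% names(depth_tbl) && length(unique(depth_tbl[[col]])) == 1L)
      depth_tbl[[col]][1] else NA_character_
  }
  structure(
    list(
      accession_id = get_const("accession_id"),
      condition = get_const("condition"),
      slope_coefficient = slope,
      slope_sd = slope_sd,
      n_seedlings = length(unique(gains$seedling_id)),
      mean_gain_per_day = mean_gain,
      cessation_flag = slope < 0,
      excluded_seedlings = excluded,
      pooling = pooling
    ),
    class = "slope_result"
  )
}

#' Classify the root response to B deficiency
#'
#' Non-cessation iff the deficient-condition slope coefficient is
#' nonnegative (zero is assigned to non-cessation: only a negative
#' acceleration of root growth counts as cessation). The
#' sufficient-condition slope is reported for context only and does not
#' enter the call.
#'
#' @param slope_deficient slope coefficient under the B-deficient
#'   condition (required, finite).
#' @param slope_sufficient optional slope under the sufficient condition.
#' @return list with `response` (`"cessation"` or `"non_cessation"`),
#'   `slope_deficient`, `slope_sufficient`.
#' @export
#' @examples
#' classify_root_response(0.1)$response   # non_cessation
#' classify_root_response(-0.5)$response  # cessation
classify_root_response <- function(slope_deficient, slope_sufficient = NA) {
  if (missing(slope_deficient) || length(slope_deficient) != 1L ||
      !is.finite(slope_deficient)) {
    abort_boreff("deficient-condition slope is required and must be finite",
                 "boreff_data_error")
  }
  list(
    response = if (slope_deficient >= 0) "non_cessation" else "cessation",
    slope_deficient = slope_deficient,
    slope_sufficient = slope_sufficient
  )
}
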