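# Windowed relative growth rates on projected leaf area, and detection of
# B-deficiency-induced growth arrest.
#
# RGR over a window (t1, t2) is the classical two-point form on natural
# logs: rgr = (ln A(t2) - ln A(t1)) / (t2 - t1), in day^-1.

# log-area at day t, linearly interpolating single-day gaps on log scale
.log_area_at <- function(das, area, t) {
  if (any(area <= 0, na.rm = TRUE)) {
    abort_boreff("nonpositive projected area in series", "boreff_data_error")
  }
  if (t %in% das) return(log(area[match(t, das)]))
  lo <- max(das[das < t], -Inf)
  hi <- min(das[das > t], Inf)
  if (!is.finite(lo) || !is.finite(hi) || (hi - lo) > 2) {
    abort_boreff(
      sprintf("day %s not observed and not bracketed within a 1-day gap", t),
      "boreff_data_error"
    )
  }
  la <- log(area[match(lo, das)])
  lb <- log(area[match(hi, das)])
  la + (lb - la) * (t - lo) / (hi - lo)
}

#' Two-point relative growth rate
#'
#' \eqn{RGR = (\ln A(t_2) - \ln A(t_1)) / (t_2 - t_1)} on projected area,
#' natural log, units day\eqn{^{-1}}. Missing imaging days are linearly
#' interpolated on log-area when the gap is at most one day; longer gaps
#' are errors. The result is invariant to rescaling the area units and
#' satisfies the chaining identity: the RGR over (a, c) is the
#' duration-weighted mean of the RGRs over (a, b) and (b, c).
#'
#' @param series a data frame with columns `das` and `area` (e.g. from
#'   [simulate_growth_series()]).
#' @param t1,t2 window endpoints in DAS, `t2 > t1`.
#' @return RGR in day^-1.
#' @export
#' @examples
#' s <- data.frame(das = c(4, 7), area = c(100, 200))
#' compute_rgr(s, 4, 7)  # log(2) / 3
compute_rgr <- function(series, t1, t2) {
  stopifnot(all(c("das", "area") %in% names(series)))
  if (t2 <= t1) {
    abort_boreff("`t2` must exceed `t1`", "boreff_config_error")
  }
  ord <- order(series$das)
  das <- series$das[ord]
  area <- series$area[ord]
  (.log_area_at(das, area, t2) - .log_area_at(das, area, t1)) / (t2 - t1)
}

#' Windowed RGR table with group summaries
#'
#' Computes the RGR per plant for each analysis window (default the early-
#' and late-stress windows 4-7 and 10-13 DAS), then summarises per
#' accession x treatment x window (mean, SD, n). With `letters = TRUE`,
#' groups within each window are compared by one-way ANOVA with
#' Bonferroni-adjusted pairwise t-tests and annotated with compact grouping
#' letters (groups sharing a letter do not differ at `alpha`).
#'
#' Plants whose series does not cover a window are skipped for that window
#' and reported in `skipped`; the run continues.
#'
#' @param series_tbl long table with columns `plant_id`, `accession_id`,
#'   `treatment`, `das`, `area`.
#' @param windows list of `c(t1, t2)` windows (default
#'   `list(c(4, 7), c(10, 13))`).
#' @param letters add Bonferroni grouping letters per window (default
#'   FALSE; groups are accession x treatment).
#' @param alpha significance level for the letters.
#' @return list with `per_plant` (plant x window RGR rows with an
#'   `arrest_flag` column set by `rgr < arrest_epsilon`), `summary`
#'   (group means), and `skipped`.
#' @param arrest_epsilon threshold below which a window RGR is flagged as
#'   arrested growth (day^-1, default 0.02).
#' @export
rgr_by_windows <- function(series_tbl,
                           windows = list(c(4, 7), c(10, 13)),
                           letters = FALSE,
                           alpha = 0.05,
                           arrest_epsilon = 0.02) {
  req <- c("plant_id", "accession_id", "treatment", "das", "area")
  stopifnot(all(req %in% names(series_tbl)))
  plants <- dplyr::distinct(series_tbl[, c("plant_id", "accession_id",
                                           "treatment")])
  rows <- list()
  skipped <- list()
  for (i in seq_len(nrow(plants))) {
    p <- plants$plant_id[i]
    s <- series_tbl[series_tbl$plant_id == p, ]
    for (w in windows) {
      r <- tryCatch(compute_rgr(s, w[1], w[2]), boreff_error = function(e) e)
      key <- paste0(p, ":", w[1], "-", w[2])
      if (inherits(r, "condition")) {
        skipped[[key]] <- tibble::tibble(
          plant_id = p, t1 = w[1], t2 = w[2], reason = conditionMessage(r))
      } else {
        rows[[key]] <- tibble::tibble(
          plant_id = p,
          accession_id = plants$accession_id[i],
          treatment = plants$treatment[i],
          t1 = w[1], t2 = w[2],
          rgr_per_day = r,
          arrest_flag = r < arrest_epsilon
        )
      }
    }
  }
  per_plant <- dplyr::bind_rows(rows)
  summary <- per_plant |>
    dplyr::group_by(.data$accession_id, .data$treatment, .data$t1, .data$t2) |>
    dplyr::summarise(
      mean_rgr = mean(.data$rgr_per_day),
      sd_rgr = sd(.data$rgr_per_day),
      n = dplyr::n(),
      .groups = "drop"
    )
  if (isTRUE(letters)) {
    summary$group_letter <- NA_character_
    for (w in windows) {
      sub <- per_plant[per_plant$t1 == w[1] & per_plant$t2 == w[2], ]
      grp <- factor(paste(sub$accession_id, sub$treatment, sep = "."))
      lev <- levels(grp)
      if (length(lev) < 2L || all(sd(sub$rgr_per_day) == 0)) {
        lett <- setNames(rep("a", length(lev)), lev)
      } else {
        pw <- suppressWarnings(
          pairwise.t.test(sub$rgr_per_day, grp,
                          p.adjust.method = "bonferroni")$p.value)
        pw[is.na(pw)] <- 1
        lett <- letter_groups(pw, lev, alpha)
      }
      key <- paste(summary$accession_id, summary$treatment, sep = ".")
      sel <- summary$t1 == w[1] & summary$t2 == w[2]
      summary$group_letter[sel] <- lett[key[sel]]
    }
  }
  skipped <- if (length(skipped) > 0) dplyr::bind_rows(skipped) else
    tibble::tibble(plant_id = character(), t1 = numeric(), t2 = numeric(),
                   reason = character())
  list(per_plant = per_plant, summary = summary, skipped = skipped)
}

#' Detect growth arrest in a projected-area series
#'
#' Scans the series for the earliest day `d` such that the RGR over
#' `(d, d + window_len)` falls below `epsilon`; a B-inefficient plant under
#' deficiency freezes its area (arrest at 9 DAS in the screen), so its
#' windowed RGR collapses to ~0 while healthy growth stays well above any
#' sensible epsilon.
#'
#' @param series data frame with `das` and `area`.
#' @param epsilon RGR threshold in day^-1 (default 0.02; must be > 0).
#' @param window_len window length in days (default 3).
#' @return list with `arrest_flag` (logical) and `arrest_das` (earliest
#'   arrest day, or `NA` if none).
#' @export
#' @examples
#' s <- simulate_growth_series("inefficient", "B0", seed = 1,
#'                             area_noise_cv = 0)
#' detect_growth_arrest(s)
detect_growth_arrest <- function(series, epsilon = 0.02, window_len = 3L) {
  stopifnot(all(c("das", "area") %in% names(series)))
  if (length(epsilon) != 1L || !is.finite(epsilon) || epsilon <= 0) {
    abort_boreff("`epsilon` must be a single positive number",
                 "boreff_config_error")
  }
  check_count(window_len, "window_len", min = 1L)
  das <- sort(unique(series$das))
  if (length(das) < window_len + 1L) {
    abort_boreff("series shorter than window_len + 1 points",
                 "boreff_data_error")
  }
  starts <- das[das + window_len <= max(das)]
  for (d in starts) {
    r <- tryCatch(compute_rgr(series, d, d + window_len),
                  boreff_error = function(e) NA_real_)
    if (is.finite(r) && r < epsilon) {
      return(list(arrest_flag = TRUE, arrest_das = d))
    }
  }
  list(arrest_flag = FALSE, arrest_das = NA_real_)
}
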