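# Boron-efficiency-index (BEI) scoring, classification and panel ranking.
#
# BEI = (mean DW_B0 / mean DW_B1) * (mean L1_B0 / mean L1_B1)
#
# Ratio of condition means (never mean of per-plant ratios): the index is
# defined on mean values, and replicates are not paired across soil
# conditions. An accession is B-efficient iff BEI >= threshold (0.7).

#' Condition means for one accession under one treatment
#'
#' Arithmetic means of dry weight and first-leaf length over the replicates
#' of one accession x treatment cell, with a minimum-replication check
#' (the screen used at least 10-12 plants per accession and condition).
#' Missing DW or L1 values are excluded from their mean and counted.
#'
#' @param measurements measurement table with columns `accession_id`,
#'   `treatment`, `DW_mg`, `L1_mm` (the schema of [generate_panel()]).
#' @param accession accession id.
#' @param treatment treatment label.
#' @param min_n minimum replicate count (default 10).
#' @return a list of class `condition_means`: `accession_id`, `treatment`,
#'   `mean_DW_mg`, `mean_L1_mm`, `n_plants`, `n_missing_dw`, `n_missing_l1`.
#' @export
condition_means <- function(measurements, accession, treatment, min_n = 10L) {
  rows <- measurements[measurements$accession_id == accession &
                         measurements$treatment == treatment, ]
  if (nrow(rows) == 0L) {
    abort_boreff(
      sprintf("no measurements for accession %s under %s", accession, treatment),
      "boreff_data_error"
    )
  }
  dw <- rows$DW_mg
  l1 <- rows$L1_mm
  n_missing_dw <- sum(is.na(dw))
  n_missing_l1 <- sum(is.na(l1))
  n <- nrow(rows)
  if (n < min_n) {
    abort_boreff(
      sprintf("insufficient replication for accession %s under %s: n = %d < %d",
              accession, treatment, n, as.integer(min_n)),
      "boreff_replication_error"
    )
  }
  structure(
    list(
      accession_id = accession,
      treatment = treatment,
      mean_DW_mg = mean(dw, na.rm = TRUE),
      mean_L1_mm = mean(l1, na.rm = TRUE),
      n_plants = n,
      n_missing_dw = n_missing_dw,
      n_missing_l1 = n_missing_l1
    ),
    class = "condition_means"
  )
}

#' Compute the boron-efficiency index from condition means
#'
#' `bei = (mean_DW_B0 / mean_DW_B1) * (mean_L1_B0 / mean_L1_B1)`. Both
#' component ratios are reported. The index is dimensionless and invariant
#' to any common rescaling of all dry weights or all leaf lengths. Values
#' above 1 are reported as-is.
#'
#' @param means_B0 [condition_means()] under the deficient condition.
#' @param means_B1 [condition_means()] under the adequate condition.
#' @return a list of class `bei_result`: `accession_id`, `dw_ratio`,
#'   `l1_ratio`, `bei`, `n_B0`, `n_B1` (classification added by
#'   [classify_accession()] / [rank_panel()]).
#' @export
#' @examples
#' b0 <- structure(list(accession_id = "A", treatment = "B0",
#'                      mean_DW_mg = 40, mean_L1_mm = 60, n_plants = 12),
#'                 class = "condition_means")
#' b1 <- structure(list(accession_id = "A", treatment = "B1",
#'                      mean_DW_mg = 50, mean_L1_mm = 80, n_plants = 12),
#'                 class = "condition_means")
#' compute_bei(b0, b1)$bei  # 0.8 * 0.75 = 0.6
compute_bei <- function(means_B0, means_B1) {
  stopifnot(inherits(means_B0, "condition_means"),
            inherits(means_B1, "condition_means"))
  if (!identical(means_B0$accession_id, means_B1$accession_id)) {
    abort_boreff("condition means come from different accessions",
                 "boreff_data_error")
  }
  if (!is.finite(means_B1$mean_DW_mg) || means_B1$mean_DW_mg <= 0 ||
      !is.finite(means_B1$mean_L1_mm) || means_B1$mean_L1_mm <= 0) {
    abort_boreff(
      sprintf("degenerate reference means for accession %s (DW or L1 <= 0)",
              means_B0$accession_id),
      "boreff_degenerate_error"
    )
  }
  dw_ratio <- means_B0$mean_DW_mg / means_B1$mean_DW_mg
  l1_ratio <- means_B0$mean_L1_mm / means_B1$mean_L1_mm
  structure(
    list(
      accession_id = means_B0$accession_id,
      dw_ratio = dw_ratio,
      l1_ratio = l1_ratio,
      bei = dw_ratio * l1_ratio,
      n_B0 = means_B0$n_plants,
      n_B1 = means_B1$n_plants
    ),
    class = "bei_result"
  )
}

#' Classify an accession from its BEI
#'
#' Efficient iff `bei >= threshold`, inclusive: the classification rule is
#' "BEI >= 0.7 is B-efficient", so an index of exactly 0.7 is efficient.
#'
#' @param bei boron-efficiency index (finite, >= 0); vectorised.
#' @param threshold efficiency threshold (default 0.7).
#' @return character vector, `"efficient"` or `"inefficient"`.
#' @export
#' @examples
#' classify_accession(c(0.8800, 0.0005, 0.7))
classify_accession <- function(bei, threshold = 0.7) {
  if (any(!is.finite(bei)) || any(bei < 0)) {
    abort_boreff("`bei` must be finite and >= 0", "boreff_data_error")
  }
  check_positive(threshold, "threshold")
  ifelse(bei >= threshold, "efficient", "inefficient")
}

#' Score, classify and rank a panel
#'
#' Computes one BEI per accession with sufficient replication under both
#' the deficient and the reference treatment, classifies with
#' [classify_accession()], and ranks by descending BEI (ties broken by
#' accession id, so output order is deterministic). Accessions failing the
#' replication minimum are listed separately, never silently dropped.
#'
#' @param measurements measurement table (schema of [generate_panel()]).
#' @param threshold efficiency threshold (default 0.7).
#' @param min_n minimum replicates per condition (default 10).
#' @param deficient,reference treatment labels (defaults `"B0"`, `"B1"`).
#' @return a list with `results` (tibble: `accession_id`, `dw_ratio`,
#'   `l1_ratio`, `bei`, `n_B0`, `n_B1`, `classification`, sorted by
#'   descending `bei`) and `excluded` (tibble: `accession_id`, `reason`).
#' @export
rank_panel <- function(measurements, threshold = 0.7, min_n = 10L,
                       deficient = "B0", reference = "B1") {
  accs <- sort(unique(measurements$accession_id))
  if (length(accs) == 0L) {
    abort_boreff("no accessions in measurement table", "boreff_data_error")
  }
  res <- list()
  excl <- list()
  for (a in accs) {
    r <- tryCatch({
      m0 <- condition_means(measurements, a, deficient, min_n)
      m1 <- condition_means(measurements, a, reference, min_n)
      compute_bei(m0, m1)
    }, boreff_error = function(e) e)
    if (inherits(r, "bei_result")) {
      res[[a]] <- tibble::tibble(
        accession_id = r$accession_id, dw_ratio = r$dw_ratio,
        l1_ratio = r$l1_ratio, bei = r$bei, n_B0 = r$n_B0, n_B1 = r$n_B1
      )
    } else {
      excl[[a]] <- tibble::tibble(accession_id = a,
                                  reason = conditionMessage(r))
    }
  }
  if (length(res) == 0L) {
    abort_boreff("no accession passed the replication minimum",
                 "boreff_replication_error")
  }
  results <- dplyr::bind_rows(res)
  results$classification <- classify_accession(results$bei, threshold)
  results <- dplyr::arrange(results, dplyr::desc(.data$bei),
                            .data$accession_id)
  excluded <- if (length(excl) > 0) dplyr::bind_rows(excl) else
    tibble::tibble(accession_id = character(), reason = character())
  list(results = results, excluded = excluded)
}

#' Classify a table of precomputed indices
#'
#' For classification-only runs on an externally computed index table
#' (e.g. a published ranking), applies the threshold rule and sorts.
#'
#' @param bei_table data frame with `accession_id` and `bei`.
#' @param threshold efficiency threshold (default 0.7).
#' @return tibble sorted by descending `bei` with a `classification` column.
#' @export
#' @examples
#' classify_bei_table(data.frame(
#'   accession_id = c("CR2262", "CR3195", "CR2280", "CR2267", "CR2285"),
#'   bei = c(0.0005, 0.10, 0.7039, 0.7059, 0.8800)))
classify_bei_table <- function(bei_table, threshold = 0.7) {
  stopifnot(all(c("accession_id", "bei") %in% names(bei_table)))
  out <- tibble::as_tibble(bei_table)
  out$classification <- classify_accession(out$bei, threshold)
  dplyr::arrange(out, dplyr::desc(.data$bei), .data$accession_id)
}

#' Correlation of image-derived area with fresh weight
#'
#' Pearson product-moment correlation between the projected top-view leaf
#' area and the physically measured plant fresh weight — the validation
#' used to trust area as a biomass proxy.
#'
#' @param area_at_day numeric vector of per-plant projected areas.
#' @param fresh_weights paired numeric vector of fresh weights.
#' @return list with `r`, `p_value`, `n`.
#' @export
area_weight_correlation <- function(area_at_day, fresh_weights) {
  ok <- is.finite(area_at_day) & is.finite(fresh_weights)
  x <- area_at_day[ok]
  y <- fresh_weights[ok]
  if (length(x) < 3L) {
    abort_boreff("need at least 3 complete pairs", "boreff_data_error")
  }
  if (var(x) == 0 || var(y) == 0) {
    abort_boreff("zero variance in area or fresh weight",
                 "boreff_data_error")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
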