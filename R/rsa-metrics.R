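# Root-system-architecture metrics from traced polylines, and the
# Table-shaped nutrient-deficiency response summary.

#' RSA metrics from a root trace
#'
#' Computes the five standard traits from polyline traces: primary-root
#' (PR) length, first-order lateral-root (1LR) number, total 1LR length,
#' average 1LR length, and 1LR density (laterals per cm PR). Lengths are
#' Euclidean arclengths of the polylines, so they are invariant under
#' rigid rotation/translation of the trace. With no laterals the average
#' lateral length is reported missing (`NA`), not 0, while density is 0.
#'
#' @param trace a `root_trace` (from [simulate_root_trace()]) or a list
#'   with `primary` (n x 2 matrix) and `laterals` (list of matrices).
#' @param plant_id identifier carried into the output.
#' @return a one-row tibble: `plant_id`, `pr_length_cm`, `lr_count`,
#'   `total_lr_length_cm`, `avg_lr_length_cm`, `lr_density_per_cm`.
#' @export
#' @examples
#' tr <- simulate_root_trace(5, 10, 2, seed = 1)
#' trace_metrics(tr)
trace_metrics <- function(trace, plant_id = "plant_1") {
  if (!is.list(trace) || is.null(trace$primary)) {
    abort_boreff("`trace` must contain a `primary` polyline",
                 "boreff_data_error")
  }
  pr <- polyline_length(trace$primary)
  if (pr <= 0) {
    abort_boreff("zero-length primary root", "boreff_data_error")
  }
  laterals <- trace$laterals %||% list()
  lr_count <- length(laterals)
  lr_lengths <- vapply(laterals, polyline_length, numeric(1))
  total_lr <- sum(lr_lengths)
  tibble::tibble(
    plant_id = plant_id,
    pr_length_cm = pr,
    lr_count = lr_count,
    total_lr_length_cm = total_lr,
    avg_lr_length_cm = if (lr_count > 0) total_lr / lr_count else NA_real_,
    lr_density_per_cm = lr_count / pr
  )
}

#' RSA summary table with significance marks
#'
#' Mean +/- SD per cultivar x condition cell for each of the five RSA
#' traits, with a per-trait one-way ANOVA of each deficiency condition
#' against the control condition within the same cultivar; cells with
#' p < `alpha` are starred. Average lateral length is computed per plant
#' and then averaged across plants (mean of per-plant ratios), which is
#' why a printed cell mean need not equal total/count of the other cell
#' means. Cells with fewer than 2 plants are flagged and never starred.
#'
#' @param metrics_tbl table of per-plant metrics (the [trace_metrics()]
#'   columns) plus `cultivar` and `condition` columns.
#' @param control label of the control condition (default `"none"`).
#' @param alpha significance level (default 0.05).
#' @return tibble with one row per cultivar x condition x trait:
#'   `mean`, `sd`, `n`, `p_value` (NA for the control row and flagged
#'   cells), `significant`, `flagged` (n < 2).
#' @export
rsa_summary <- function(metrics_tbl, control = "none", alpha = 0.05) {
  req <- c("cultivar", "condition", "pr_length_cm", "lr_count",
           "total_lr_length_cm", "avg_lr_length_cm", "lr_density_per_cm")
  stopifnot(all(req %in% names(metrics_tbl)))
  traits <- req[-(1:2)]
  long <- tidyr::pivot_longer(
    metrics_tbl[, req], dplyr::all_of(traits),
    names_to = "trait", values_to = "value"
  )
  cells <- long |>
    dplyr::group_by(.data$cultivar, .data$condition, .data$trait) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)),
      .groups = "drop"
    )
  cells$p_value <- NA_real_
  cells$flagged <- cells$n < 2L
  for (i in seq_len(nrow(cells))) {
    if (cells$condition[i] == control || cells$flagged[i]) next
    ctrl <- long$value[long$cultivar == cells$cultivar[i] &
                         long$condition == control &
                         long$trait == cells$trait[i]]
    trt <- long$value[long$cultivar == cells$cultivar[i] &
                        long$condition == cells$condition[i] &
                        long$trait == cells$trait[i]]
    ctrl <- ctrl[!is.na(ctrl)]
    trt <- trt[!is.na(trt)]
    if (length(ctrl) < 2L || length(trt) < 2L) {
      cells$flagged[i] <- TRUE
      next
    }
    vals <- c(ctrl, trt)
    grp <- factor(rep(c("control", "treatment"), c(length(ctrl), length(trt))))
    if (sd(vals) == 0) {
      cells$p_value[i] <- 1
    } else {
      fit <- aov(vals ~ grp)
      cells$p_value[i] <- summary(fit)[[1]][["Pr(>F)"]][1]
    }
  }
  cells$significant <- !is.na(cells$p_value) & cells$p_value < alpha
  cells
}

#' Read / write root traces as JSON
#'
#' Traces are interchanged as a JSON list of objects with a `primary`
#' polyline (list of `[x, y]` pairs, cm) and a `laterals` list of
#' polylines.
#'
#' @param traces named list of `root_trace` objects (names become ids).
#' @param path file path.
#' @return `write_traces_json()` returns `path` invisibly;
#'   `read_traces_json()` returns a named list of traces.
#' @export
write_traces_json <- function(traces, path) {
  payload <- lapply(traces, function(tr) {
    list(primary = unname(apply(tr$primary, 1, as.numeric, simplify = FALSE)),
         laterals = lapply(tr$laterals %||% list(), function(l) {
           unname(apply(l, 1, as.numeric, simplify = FALSE))
         }))
  })
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_traces_json
#' @export
read_traces_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(tr) {
    list(
      primary = do.call(rbind, lapply(tr$primary, function(p) {
        as.numeric(unlist(p))
      })),
      laterals = lapply(tr$laterals, function(l) {
        do.call(rbind, lapply(l, function(p) as.numeric(unlist(p))))
      })
    )
  })
}
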