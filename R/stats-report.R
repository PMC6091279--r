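# Replicate-mean aggregation, PCA of the trait matrix, and the
# treatment-separation score, plus the routine comparison helpers
# (t-test / one-way ANOVA / Bonferroni).

#' Replicate-mean trait matrix
#'
#' Arithmetic means over replicates for each cultivar x treatment x
#' imaging day and trait, pivoted to one row per cultivar x treatment x
#' day (default) or — with `day_handling = "columns"` — one row per
#' cultivar x treatment with day-expanded trait columns
#' (`<trait>_d<day>`). Rows with any missing cell after aggregation are
#' dropped and reported.
#'
#' @param trait_tbl long table with columns `cultivar`, `treatment`,
#'   `day`, `replicate` and one column per trait (all other columns are
#'   treated as traits).
#' @param day_handling `"rows"` (default) or `"columns"`.
#' @return list with `matrix` (numeric matrix, rownames
#'   `cultivar.treatment[.day]`), `meta` (tibble of row metadata) and
#'   `dropped` (character vector of dropped row keys).
#' @export
replicate_mean_matrix <- function(trait_tbl,
                                  day_handling = c("rows", "columns")) {
  day_handling <- match.arg(day_handling)
  key <- c("cultivar", "treatment", "day", "replicate")
  stopifnot(all(key %in% names(trait_tbl)))
  traits <- setdiff(names(trait_tbl), key)
  if (length(traits) < 2L) {
    abort_boreff("need at least 2 trait columns", "boreff_data_error")
  }
  agg <- trait_tbl |>
    dplyr::group_by(.data$cultivar, .data$treatment, .data$day) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(traits),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  if (day_handling == "columns") {
    agg <- tidyr::pivot_wider(
      agg, id_cols = c("cultivar", "treatment"),
      names_from = "day", values_from = dplyr::all_of(traits),
      names_glue = "{.value}_d{day}"
    )
    meta <- agg[, c("cultivar", "treatment")]
    mat <- as.matrix(agg[, setdiff(names(agg), c("cultivar", "treatment"))])
    rownames(mat) <- paste(meta$cultivar, meta$treatment, sep = ".")
  } else {
    meta <- agg[, c("cultivar", "treatment", "day")]
    mat <- as.matrix(agg[, traits])
    rownames(mat) <- paste(meta$cultivar, meta$treatment, meta$day,
                           sep = ".")
  }
  complete <- apply(mat, 1, function(r) all(is.finite(r)))
  dropped <- rownames(mat)[!complete]
  list(matrix = mat[complete, , drop = FALSE],
       meta = meta[complete, , drop = FALSE],
       dropped = dropped)
}

#' PCA of a trait matrix
#'
#' Column-centred (and, by default, z-scored — the traits mix pixel counts
#' and colour means on incommensurate scales) principal component analysis
#' via singular value decomposition. Loadings are orthonormal; each
#' loading vector's largest-magnitude element is made positive, so output
#' signs are deterministic. Variance-explained fractions are nonnegative,
#' non-increasing and sum to 1.
#'
#' @param mat numeric matrix, >= 3 rows and >= 2 columns, finite values.
#' @param standardize z-score the columns (default TRUE). A constant
#'   column under standardisation is an error naming the column.
#' @return list of class `trait_pca`: `scores` (rows x components),
#'   `loadings` (traits x components), `variance_explained`.
#' @export
pca_traits <- function(mat, standardize = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3L || ncol(mat) < 2L || !all(is.finite(mat))) {
    abort_boreff("matrix must be >= 3 x >= 2 with finite values",
                 "boreff_data_error")
  }
  if (standardize) {
    sds <- apply(mat, 2, sd)
    if (any(sds == 0)) {
      bad <- colnames(mat)[sds == 0] %||% which(sds == 0)
      abort_boreff(
        paste0("constant column(s) under standardization: ",
               paste(bad, collapse = ", ")),
        "boreff_data_error"
      )
    }
  }
  fit <- prcomp(mat, center = TRUE, scale. = standardize)
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings, variance_explained = ve,
         standardized = standardize),
    class = "trait_pca"
  )
}

#' Treatment separation score on principal components
#'
#' Quantifies how cleanly the B treatments separate for one cultivar in PC
#' space: the root-mean-square spread of the treatment centroids around
#' their grand centroid, divided by the pooled within-treatment spread.
#' B-inefficient cultivars, whose deficient plants collapse, separate
#' strongly (high score); efficient cultivars cluster together (low
#' score). With identical centroids the score is 0; with zero
#' within-treatment spread but distinct centroids it is `Inf`.
#'
#' @param scores numeric matrix (or vector) of component scores for the
#'   cultivar's rows.
#' @param treatments treatment label per row; at least 2 distinct labels.
#' @param components which score columns to use (default 1, i.e. PC1).
#' @return separation score (single number, >= 0).
#' @export
treatment_separation_index <- function(scores, treatments, components = 1) {
  scores <- as.matrix(scores)
  treatments <- as.character(treatments)
  if (nrow(scores) != length(treatments)) {
    abort_boreff("scores and treatment labels differ in length",
                 "boreff_data_error")
  }
  if (length(unique(treatments)) < 2L) {
    abort_boreff("need at least two treatments", "boreff_data_error")
  }
  x <- scores[, components, drop = FALSE]
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(x)), treatments),
                                     function(i) colMeans(x[i, , drop = FALSE])))
  grand <- colMeans(centroids)
  between <- sqrt(mean(rowSums(sweep(centroids, 2, grand)^2)))
  within_dev <- unlist(lapply(split(seq_len(nrow(x)), treatments), function(i) {
    xi <- x[i, , drop = FALSE]
    rowSums(sweep(xi, 2, colMeans(xi))^2)
  }))
  within <- sqrt(mean(within_dev))
  if (between == 0) return(0)
  between / within
}

#' Routine group-comparison helpers
#'
#' Thin wrappers over the standard tests used in screen reporting:
#' `compare_two_groups()` is a two-sample t-test, `anova_groups()` a
#' one-way ANOVA, and `bonferroni_letters()` Bonferroni-adjusted pairwise
#' t-tests condensed to compact grouping letters.
#'
#' @param x,y numeric vectors (two-group comparison).
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @param alpha significance level for the letters.
#' @return `compare_two_groups()` and `anova_groups()` return the p-value;
#'   `bonferroni_letters()` a named character vector of letters per group.
#' @export
compare_two_groups <- function(x, y) {
  stats::t.test(x, y)$p.value
}

#' @rdname compare_two_groups
#' @export
anova_groups <- function(values, groups) {
  fit <- aov(values ~ factor(groups))
  summary(fit)[[1]][["Pr(>F)"]][1]
}

#' @rdname compare_two_groups
#' @export
bonferroni_letters <- function(values, groups, alpha = 0.05) {
  grp <- factor(groups)
  lev <- levels(grp)
  if (length(lev) < 2L) return(setNames("a", lev))
  pw <- suppressWarnings(
    pairwise.t.test(values, grp, p.adjust.method = "bonferroni")$p.value)
  pw[is.na(pw)] <- 1
  letter_groups(pw, lev, alpha)
}
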