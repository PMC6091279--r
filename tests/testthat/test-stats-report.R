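# Replicate-mean aggregation, PCA and the treatment-separation score.

make_trait_tbl <- function(n_cultivars = 13, n_treatments = 3, n_days = 9,
                           n_reps = 8, seed = 1) {
  set.seed(seed)
  g <- tidyr::expand_grid(
    cultivar = sprintf("C%02d", seq_len(n_cultivars)),
    treatment = c("B0", "B1", "B2")[seq_len(n_treatments)],
    day = 5:(4 + n_days),
    replicate = seq_len(n_reps)
  )
  g$projected_area_px <- exp(rnorm(nrow(g), 8, 0.5))
  g$border_length_px <- sqrt(g$projected_area_px) * 6
  g$mean_hue <- rnorm(nrow(g), 120, 5)
  g
}

test_that("replicate means aggregate correctly with the expected row
           cardinality", {
  tbl <- make_trait_tbl()
  rm <- replicate_mean_matrix(tbl)
  expect_equal(nrow(rm$matrix), 13 * 3 * 9)  # cultivar x treatment x day
  expect_equal(ncol(rm$matrix), 3)
  # equal replicates collapse to the value; {1,3} averages to 2
  small <- tibble::tibble(
    cultivar = "C1", treatment = "B1", day = 5, replicate = 1:2,
    t1 = c(1, 3), t2 = c(4, 4)
  )
  rm2 <- replicate_mean_matrix(small)
  expect_equal(unname(rm2$matrix[1, ]), c(2, 4))

  wide <- replicate_mean_matrix(tbl, day_handling = "columns")
  expect_equal(nrow(wide$matrix), 13 * 3)
  expect_equal(ncol(wide$matrix), 3 * 9)
})

test_that("rows with missing cells are dropped with a log", {
  tbl <- make_trait_tbl(n_cultivars = 2, n_days = 2)
  tbl$mean_hue[tbl$cultivar == "C01" & tbl$treatment == "B0" &
                 tbl$day == 5] <- NA
  rm <- replicate_mean_matrix(tbl)
  expect_equal(rm$dropped, "C01.B0.5")
  expect_equal(nrow(rm$matrix), 2 * 3 * 2 - 1)
})

test_that("PCA satisfies its invariants and matches an independent
           eigendecomposition oracle", {
  set.seed(42)
  mat <- matrix(rnorm(40), 10, 4,
                dimnames = list(NULL, paste0("t", 1:4)))
  p <- pca_traits(mat, standardize = TRUE)
  ve <- p$variance_explained
  expect_true(all(ve >= 0))
  expect_true(all(diff(ve) <= 1e-12))
  expect_equal(sum(ve), 1, tolerance = 1e-9)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-9,
               ignore_attr = TRUE)
  # oracle: eigenvalues of the correlation (z-scored covariance) matrix
  z <- scale(mat)
  ev <- eigen(stats::cov(z), symmetric = TRUE)$values
  expect_equal(ve, ev / sum(ev), tolerance = 1e-9)
  # scores reproduce: X_std %*% loadings
  expect_equal(unname(p$scores), unname(z %*% p$loadings),
               tolerance = 1e-9)
})

test_that("PCA sign convention and degenerate inputs behave", {
  set.seed(7)
  mat <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- pca_traits(mat)
  peak <- apply(p$loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(peak > 0))
  # row reordering leaves loadings identical and permutes scores
  perm <- sample(10)
  p2 <- pca_traits(mat[perm, ])
  expect_equal(p2$loadings, p$loadings, tolerance = 1e-9)
  expect_equal(unname(p2$scores), unname(p$scores[perm, ]),
               tolerance = 1e-9)
  # one-directional data puts all variance on PC1
  line <- outer(1:6, c(1, 2, 3))
  pl <- pca_traits(line, standardize = FALSE)
  expect_equal(pl$variance_explained[1], 1, tolerance = 1e-12)
  const <- cbind(x = rnorm(5), y = rep(1, 5))
  expect_error(pca_traits(const), "constant column.*y")
  expect_error(pca_traits(mat[1:2, ]), ">= 3")
})

test_that("separation score matches hand ratios and boundary cases", {
  # two treatments at +/-10 with within-spread 1 -> score 10
  scores <- c(-11, -9, 9, 11)
  trt <- c("B0", "B0", "B1", "B1")
  expect_equal(treatment_separation_index(scores, trt), 10)
  # identical positions -> 0
  expect_equal(treatment_separation_index(c(1, 1, 1, 1), trt), 0)
  expect_error(treatment_separation_index(1:4, rep("B0", 4)),
               "two treatments")
})

test_that("inefficient cultivars separate treatments more than efficient
           ones under default generator effects", {
  rows <- list()
  for (acc in sprintf("A%d", 1:4)) {
    cls <- if (acc %in% c("A1", "A2")) "inefficient" else "efficient"
    for (trt in c("B0", "B1", "B2")) for (r in 1:4) {
      rows[[paste(acc, trt, r)]] <- simulate_growth_series(
        cls, trt, seed = 100 + length(rows),
        plant_id = paste(acc, trt, r, sep = "_"), accession_id = acc)
    }
  }
  long <- dplyr::bind_rows(rows)
  trait_tbl <- tibble::tibble(
    cultivar = long$accession_id, treatment = long$treatment,
    day = long$das, replicate = sub(".*_", "", long$plant_id),
    area = long$area, border = long$border_length
  )
  rm <- replicate_mean_matrix(trait_tbl)
  p <- pca_traits(rm$matrix)
  sep <- vapply(sprintf("A%d", 1:4), function(a) {
    rows_a <- rm$meta$cultivar == a
    treatment_separation_index(p$scores[rows_a, , drop = FALSE],
                               rm$meta$treatment[rows_a])
  }, numeric(1))
  expect_gt(min(sep[c("A1", "A2")]), max(sep[c("A3", "A4")]))
})

test_that("comparison helpers agree with the standard tests", {
  set.seed(11)
  x <- rnorm(10)
  y <- rnorm(10, 2)
  expect_equal(compare_two_groups(x, y), stats::t.test(x, y)$p.value)
  vals <- c(x, y)
  grp <- rep(c("a", "b"), each = 10)
  expect_equal(anova_groups(vals, grp),
               summary(aov(vals ~ factor(grp)))[[1]][["Pr(>F)"]][1])
  lett <- bonferroni_letters(c(rnorm(6, 0), rnorm(6, 0), rnorm(6, 30)),
                             rep(c("g1", "g2", "g3"), each = 6))
  expect_equal(lett[["g1"]], lett[["g2"]])
  expect_false(lett[["g3"]] == lett[["g1"]])
})
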