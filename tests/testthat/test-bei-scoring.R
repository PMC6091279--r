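# BEI computation, classification, ranking and the area-FW correlation.

test_that("condition means are arithmetic means with replication checks", {
  m <- measurements_fixture(dw_b0 = c(40, 60), dw_b1 = rep(50, 12))
  cm <- condition_means(m, "A1", "B0", min_n = 2)
  expect_equal(cm$mean_DW_mg, 50)
  expect_equal(cm$n_plants, 2L)
  expect_error(condition_means(m, "A1", "B0", min_n = 10),
               "insufficient replication",
               class = "boreff_replication_error")
  expect_error(condition_means(m, "ZZ", "B0"), "no measurements")
  # missing values are excluded with a count, not propagated
  m$DW_mg[m$treatment == "B1"][1] <- NA
  cm1 <- condition_means(m, "A1", "B1", min_n = 2)
  expect_equal(cm1$n_missing_dw, 1L)
  expect_equal(cm1$mean_DW_mg, 50)
})

test_that("BEI is the product of ratio-of-means and handles degenerate
           references", {
  b <- compute_bei(cm_fixture("A", "B0", dw = 40, l1 = 60),
                   cm_fixture("A", "B1", dw = 50, l1 = 80))
  expect_equal(b$dw_ratio, 0.8)
  expect_equal(b$l1_ratio, 0.75)
  expect_equal(b$bei, 0.6)
  # identity when means are equal
  same <- compute_bei(cm_fixture("A", "B0", 50, 60),
                      cm_fixture("A", "B1", 50, 60))
  expect_equal(same$bei, 1.0)
  expect_error(
    compute_bei(cm_fixture("A", "B0", 40, 60), cm_fixture("A", "B1", 0, 80)),
    "degenerate", class = "boreff_degenerate_error")
  expect_error(
    compute_bei(cm_fixture("A", "B0", 40, 60), cm_fixture("B", "B1", 50, 80)),
    "different accessions")
})

test_that("BEI is invariant under unit rescaling of weights or lengths", {
  base <- compute_bei(cm_fixture("A", "B0", 37.5, 61),
                      cm_fixture("A", "B1", 52.1, 80.4))$bei
  # mg -> g on all DW, mm -> cm on all L1
  scaled <- compute_bei(cm_fixture("A", "B0", 0.0375, 6.1),
                        cm_fixture("A", "B1", 0.0521, 8.04))$bei
  expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("BEI increases strictly with the deficient dry-weight mean", {
  beis <- vapply(c(20, 30, 40, 50), function(dw) {
    compute_bei(cm_fixture("A", "B0", dw, 60),
                cm_fixture("A", "B1", 50, 80))$bei
  }, numeric(1))
  expect_true(all(diff(beis) > 0))
})

test_that("classification uses an inclusive 0.7 threshold", {
  expect_equal(classify_accession(c(0.8800, 0.0005, 0.7, 0.69999)),
               c("efficient", "inefficient", "efficient", "inefficient"))
  expect_error(classify_accession(-0.1), "finite")
  expect_error(classify_accession(Inf), "finite")
})

test_that("the printed worked example ranks and classifies correctly", {
  ranked <- classify_bei_table(printed_bei_table())
  expect_equal(sum(ranked$classification == "efficient"), 3L)
  expect_equal(ranked$bei[1], 0.8800)
  expect_equal(ranked$accession_id[1], "CR2285")
  expect_equal(min(ranked$bei[ranked$classification == "efficient"]), 0.7039)
})

test_that("rank_panel scores every eligible accession, sorts
           deterministically and reports exclusions", {
  panel <- generate_panel(panel_config(n_spring = 8, n_winter = 0,
                                       efficient_fraction = 0.5, seed = 21))
  meas <- panel$measurements
  # cripple one accession's replication under B0
  short <- meas$accession_id == "ACC0008" & meas$treatment == "B0" &
    meas$replicate > 5
  meas <- meas[!short, ]
  out <- rank_panel(meas)
  expect_equal(nrow(out$results), 7L)
  expect_equal(out$excluded$accession_id, "ACC0008")
  expect_match(out$excluded$reason, "insufficient replication")
  expect_true(all(diff(out$results$bei) <= 0))
  expect_error(rank_panel(meas[meas$replicate <= 2, ]),
               class = "boreff_replication_error")
})

test_that("zero-noise panel recovers ground-truth indices exactly", {
  panel <- generate_panel(panel_config(n_spring = 10, n_winter = 0,
                                       noise_cv = 0,
                                       efficient_fraction = 0.5, seed = 2))
  out <- rank_panel(panel$measurements)
  truth <- panel$ground_truth$true_bei[
    match(out$results$accession_id, panel$ground_truth$accession_id)]
  expect_equal(out$results$bei, truth, tolerance = 1e-12)
})

test_that("area-weight correlation matches closed forms and the analytic
           rho of a noisy linear relation", {
  x <- 1:20
  expect_equal(area_weight_correlation(x, 2 * x)$r, 1.0)
  expect_equal(area_weight_correlation(x, -x)$r, -1.0)
  expect_error(area_weight_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(area_weight_correlation(1:2, 2:3), "at least 3")
  # y = x + e with var(e) = sigma^2: rho = 1/sqrt(1 + sigma^2)
  set.seed(77)
  sigma <- 0.4
  xs <- rnorm(200)
  ys <- xs + rnorm(200, 0, sigma)
  rho <- 1 / sqrt(1 + sigma^2)
  expect_lt(abs(area_weight_correlation(xs, ys)$r - rho), 0.05)
})
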