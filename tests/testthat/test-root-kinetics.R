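# Root cessation assay: gains, slope coefficients, response classification.

test_that("daily gains are first differences with integrity checks", {
  expect_equal(daily_depth_gain(
    data.frame(day = 0:3, depth_cm = c(0, 1, 2, 3)))$gain_cm, c(1, 1, 1))
  expect_equal(daily_depth_gain(
    data.frame(day = 0:5, depth_cm = c(0, 2, 3.5, 4.5, 5, 5)))$gain_cm,
    c(2, 1.5, 1, 0.5, 0))
  expect_error(daily_depth_gain(data.frame(day = 0, depth_cm = 1)),
               "two depth marks")
  expect_error(daily_depth_gain(
    data.frame(seedling_id = "s9", day = 0:2, depth_cm = c(2, 1, 3))),
    "s9")
})

test_that("slope coefficient matches exact lines and pools per seedling", {
  flat <- data.frame(seedling_id = "s1", day = 0:5,
                     depth_cm = cumsum(c(0, rep(1, 5))))
  expect_equal(gain_slope_coefficient(flat)$slope_coefficient, 0)

  ramp <- data.frame(seedling_id = "s1", day = 0:5,
                     depth_cm = cumsum(c(0, 2, 1.5, 1, 0.5, 0)))
  r <- gain_slope_coefficient(ramp)
  expect_equal(r$slope_coefficient, -0.5)
  expect_true(r$cessation_flag)

  up <- data.frame(seedling_id = "s1", day = 0:3,
                   depth_cm = cumsum(c(0, 0, 1, 2)))
  expect_equal(gain_slope_coefficient(up)$slope_coefficient, 1)

  # per-seedling averaging: mean of the two exact slopes
  both <- rbind(transform(ramp, seedling_id = "a"),
                transform(up, seedling_id = "b"))
  expect_equal(gain_slope_coefficient(both)$slope_coefficient,
               mean(c(-0.5, 1)))
  expect_equal(gain_slope_coefficient(both)$n_seedlings, 2L)

  # short seedlings are excluded with a log; all excluded is an error
  short <- data.frame(seedling_id = "c", day = 0:2, depth_cm = c(0, 1, 2))
  mix <- rbind(both, short)
  expect_equal(gain_slope_coefficient(mix)$excluded_seedlings, "c")
  expect_error(gain_slope_coefficient(short), "all seedlings excluded")
})

test_that("slope is shift-invariant and scale-equivariant in the gains", {
  base_gains <- c(2, 1.7, 1.1, 0.9, 0.2)
  mk <- function(g) data.frame(seedling_id = "s", day = 0:5,
                               depth_cm = cumsum(c(0, g)))
  s0 <- gain_slope_coefficient(mk(base_gains))$slope_coefficient
  s_shift <- gain_slope_coefficient(mk(base_gains + 3))$slope_coefficient
  s_scale <- gain_slope_coefficient(mk(base_gains * 2.5))$slope_coefficient
  expect_equal(s_shift, s0, tolerance = 1e-12)
  expect_equal(s_scale, 2.5 * s0, tolerance = 1e-12)
})

test_that("OLS slope equals a brute-force grid minimiser of squared error", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    x <- seq_len(n)
    y <- rnorm(n)
    ols <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    # profile out the intercept; golden-ratio-free plain grid refinement
    sse <- function(b) {
      a <- mean(y) - b * mean(x)
      sum((y - a - b * x)^2)
    }
    lo <- ols - 2
    hi <- ols + 2
    for (pass in 1:40) {
      grid <- seq(lo, hi, length.out = 21)
      best <- grid[which.min(vapply(grid, sse, numeric(1)))]
      step <- (hi - lo) / 20
      lo <- best - step
      hi <- best + step
    }
    expect_lt(abs(best - ols), 1e-6)
    fitted <- gain_slope_coefficient(data.frame(
      seedling_id = "s", day = c(0, x), depth_cm = cumsum(c(0, pmax(y + 5, 0)))
    ))$slope_coefficient
    expect_equal(fitted,
                 sum((x - mean(x)) * (pmax(y + 5, 0) - mean(pmax(y + 5, 0)))) /
                   sum((x - mean(x))^2),
                 tolerance = 1e-9)
  }
})

test_that("root response classification follows the sign rule with zero
           assigned to non-cessation", {
  expect_equal(classify_root_response(0.1)$response, "non_cessation")
  expect_equal(classify_root_response(-0.5)$response, "cessation")
  expect_equal(classify_root_response(0)$response, "non_cessation")
  expect_error(classify_root_response(NA_real_), "finite")
  expect_error(classify_root_response(), "required")
})

test_that("mean slope sign matches the generator's gain trend in >= 95%
           of simulated accessions", {
  n_acc <- 500
  n_seedlings <- 15  # 3 plates x 5 seedlings
  correct <- logical(n_acc)
  for (a in seq_len(n_acc)) {
    cls <- if (a %% 2 == 0) "efficient" else "inefficient"
    tbl <- dplyr::bind_rows(lapply(seq_len(n_seedlings), function(j) {
      simulate_root_depth_series(cls, "deficient",
                                 seed = a * 1000 + j,
                                 seedling_id = paste0("s", j))
    }))
    truth_trend <- attr(simulate_root_depth_series(
      cls, "deficient", seed = 1), "true_gain_trend")
    fit <- gain_slope_coefficient(tbl)
    correct[a] <- sign(fit$slope_coefficient) == sign(truth_trend)
  }
  expect_gte(mean(correct), 0.95)
})
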