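# Generators: design emulation, seed determinism, zero-noise exactness and
# ground-truth bookkeeping.

test_that("panel generator emulates the screen design and records truth", {
  cfg <- panel_config(n_spring = 234L, n_winter = 356L, seed = 11)
  panel <- generate_panel(cfg)
  expect_equal(nrow(panel$manifest), 590L)
  expect_equal(sum(panel$manifest$type_label == "spring"), 234L)
  expect_equal(
    nrow(panel$measurements),
    590L * length(cfg$treatments) * cfg$replicates_per_condition
  )
  # winter types are never efficient; truth table is complete and consistent
  expect_true(all(
    panel$manifest$true_class[panel$manifest$type_label == "winter"] ==
      "inefficient"))
  expect_equal(panel$ground_truth$true_bei,
               panel$ground_truth$true_dw_ratio *
                 panel$ground_truth$true_l1_ratio)
  # invariants on the measurement table
  m <- panel$measurements
  expect_true(all(m$DW_mg <= m$FW_mg))
  expect_true(all(m$DW_mg >= 0 & m$L1_mm >= 0))
  expect_true(all(m$water_content_pct >= 0 & m$water_content_pct <= 100))
})

test_that("identical seed gives identical panels; different seed differs", {
  cfg <- panel_config(n_spring = 10L, n_winter = 5L, seed = 42)
  expect_identical(generate_panel(cfg), generate_panel(cfg))
  cfg2 <- panel_config(n_spring = 10L, n_winter = 5L, seed = 43)
  expect_false(identical(generate_panel(cfg)$measurements,
                         generate_panel(cfg2)$measurements))
})

test_that("zero-noise panels hit their parameterised ratios exactly", {
  eff <- growth_effect_params()
  cfg <- panel_config(n_spring = 6L, n_winter = 0L, noise_cv = 0,
                      efficient_fraction = 0, effect = eff, seed = 5)
  panel <- generate_panel(cfg)
  scored <- rank_panel(panel$measurements)
  expect_equal(scored$results$dw_ratio,
               rep(eff$deficiency_DW_ratio_inefficient, 6), tolerance = 1e-12)
  expect_equal(scored$results$l1_ratio,
               rep(eff$deficiency_L1_ratio_inefficient, 6), tolerance = 1e-12)
})

test_that("panel configuration is validated", {
  expect_error(panel_config(n_spring = -1, seed = 1), "n_spring")
  expect_error(panel_config(n_spring = 0, n_winter = 0, seed = 1),
               "at least one accession")
  expect_error(panel_config(treatments = c("B0", "BX"), seed = 1),
               "subset")
  expect_error(panel_config(replicates_per_condition = 0, seed = 1),
               "replicates_per_condition")
  expect_error(panel_config(efficient_fraction = 1.2, seed = 1),
               "efficient_fraction")
  expect_error(panel_config(n_spring = 2), "seed")
})

test_that("growth series freezes area at the arrest day for the
           inefficient class under deficiency", {
  s <- simulate_growth_series("inefficient", "B0", seed = 3,
                              area_noise_cv = 0)
  frozen <- s$area[s$das >= 9]
  expect_true(all(frozen == frozen[1]))
  expect_identical(attr(s, "true_arrest_das"), 9L)
  # strictly increasing before arrest (logistic monotonicity)
  pre <- s$area[s$das <= 9]
  expect_true(all(diff(pre) > 0))
})

test_that("efficient deficient trajectory equals sufficient when ratios
           are 1, and arrest outside the span errors", {
  p1 <- growth_effect_params(deficiency_DW_ratio_efficient = 1)
  a <- simulate_growth_series("efficient", "B0", p1, seed = 9,
                              area_noise_cv = 0)
  b <- simulate_growth_series("efficient", "B1", p1, seed = 9,
                              area_noise_cv = 0)
  expect_equal(a$area, b$area)
  p2 <- growth_effect_params(arrest_day_inefficient = 20L)
  expect_error(simulate_growth_series("inefficient", "B0", p2, seed = 1),
               "arrest_day")
})

test_that("root depth series reproduces the linear cessation ramp and
           keeps depth nondecreasing", {
  d <- simulate_root_depth_series("inefficient", "deficient", seed = 1,
                                  gain_noise_cv = 0, initial_gain_cm = 2)
  expect_equal(diff(d$depth_cm), c(2, 1.5, 1, 0.5, 0))
  # constant gains under sufficiency; zero-trend efficient is constant too
  s <- simulate_root_depth_series("efficient", "deficient", seed = 2,
                                  gain_noise_cv = 0, efficient_trend = 0)
  expect_equal(diff(diff(s$depth_cm)), rep(0, 4))
  # nondecreasing holds under noise for many seeds
  for (seed in 1:25) {
    x <- simulate_root_depth_series("inefficient", "deficient", seed = seed)
    expect_true(all(diff(x$depth_cm) >= 0))
  }
})

test_that("root traces have exact arclengths and are seed-reproducible", {
  tr <- simulate_root_trace(5, 10, 2, seed = 4)
  m <- trace_metrics(tr)
  expect_equal(m$pr_length_cm, 10, tolerance = 1e-9)
  expect_equal(m$total_lr_length_cm, 10, tolerance = 1e-9)
  expect_equal(m$lr_count, 5L)
  expect_identical(simulate_root_trace(3, 7, 1.5, seed = 8),
                   simulate_root_trace(3, 7, 1.5, seed = 8))
  expect_length(simulate_root_trace(0, 7, 1, seed = 1)$laterals, 0L)
  expect_error(simulate_root_trace(-1, 7, 1, seed = 1), "n_laterals")
})

test_that("rendered masks carry analytic ground truth", {
  img <- render_plant_image("disk", size = 50, canvas_px = 128)
  expect_equal(img$truth$analytic_area_px, pi * 50^2)
  sq <- render_plant_image("square", size = 100, canvas_px = 256)
  expect_equal(sum(sq$mask), 10000)
  expect_equal(sq$truth$analytic_area_px, 10000)
  expect_equal(sq$truth$analytic_perimeter_px, 400)
  # disjoint rosette: analytic area is the sum of the lobe areas
  lobes <- list(list(cx = 40, cy = 40, a = 12, b = 6),
                list(cx = 100, cy = 40, a = 10, b = 5),
                list(cx = 70, cy = 100, a = 14, b = 7))
  ros <- render_plant_image("rosette", size = lobes, canvas_px = 144)
  expect_true(ros$truth$lobes_disjoint)
  expect_equal(ros$truth$analytic_area_px,
               pi * (12 * 6 + 10 * 5 + 14 * 7))
  expect_error(render_plant_image("disk", size = 200, canvas_px = 128),
               "canvas")
})

test_that("mask and colour PNG round-trips preserve content", {
  img <- render_plant_image("disk", size = 20, canvas_px = 64)
  tmp <- withr::local_tempfile(fileext = ".png")
  write_mask_png(img$mask, tmp)
  expect_identical(read_mask_png(tmp), img$mask)
  tmpc <- withr::local_tempfile(fileext = ".png")
  write_color_png(img$color, tmpc)
  expect_equal(read_color_png(tmpc), img$color, tolerance = 1 / 255)
})
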