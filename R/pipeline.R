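# YAML-configured, seeded orchestration of the full analysis chain:
# simulate -> extract -> score -> rgr -> cessation -> rsa -> report.
# Every stage draws its seed from the single config seed via stage_seed(),
# so stages are individually reproducible and re-runs with the same config
# give identical output digests.

.default_pipeline_config <- function() {
  list(
    seed = NULL,
    panel = list(
      n_spring = 20L, n_winter = 10L,
      treatments = c("B0", "B1", "B2"),
      replicates_per_condition = 12L,
      efficient_fraction = 3 / 590,
      noise_cv = 0.15
    ),
    effect = list(),   # growth_effect_params() overrides
    phenotyping = list(
      n_accessions = 6L,  # subset re-imaged daily, 8 replicates each
      replicates = 8L,
      days = 4:13,
      windows = list(c(4, 7), c(10, 13)),
      arrest_epsilon = 0.02
    ),
    cessation = list(
      n_accessions = 6L,
      replicates = 3L,       # biological replications (plates)
      seedlings_per_replicate = 5L,  # 3 x 5 = 15 per accession-condition
      n_days = 5L
    ),
    rsa = list(n_plants = 5L, n_laterals = 8L, pr_length_cm = 7,
               lateral_length_cm = 1.2),
    images = list(n_images = 3L, shape = "disk", size = 40, canvas_px = 128L),
    scoring = list(threshold = 0.7, min_n = 10L)
  )
}

# recursive override of defaults by user config
.merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Fills defaults and checks the schema before any stage runs. The seed is
#' mandatory; unknown top-level keys are errors.
#'
#' @param config a named list (parsed YAML) or a YAML file path.
#' @return the completed configuration list.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_boreff("config must be a list or a YAML file path",
                 "boreff_config_error")
  }
  defaults <- .default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort_boreff(paste0("unknown config key(s): ",
                        paste(unknown, collapse = ", ")),
                 "boreff_config_error")
  }
  cfg <- .merge_config(defaults, config)
  if (is.null(cfg$seed)) {
    abort_boreff("config must set `seed`", "boreff_config_error")
  }
  check_count(cfg$seed, "seed")
  if (is.list(cfg$phenotyping$windows)) {
    cfg$phenotyping$windows <- lapply(cfg$phenotyping$windows, as.numeric)
  }
  cfg
}

.write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full screening pipeline
#'
#' Executes all stages in dependency order on synthetic inputs emulating
#' the screen design, writing every stage output to `out_dir` and a run
#' manifest (config snapshot, per-stage seeds, MD5 digest of every output
#' file) last. Any stage failure halts the run with an error naming the
#' stage.
#'
#' Stage outputs: `manifest.csv`, `measurements.csv`, `ground_truth.csv`
#' (simulate); `traits.csv` (extract, from rendered mask/colour PNGs also
#' written per image); `bei_results.csv` (score); `rgr.csv`,
#' `rgr_summary.csv` (rgr); `slopes.csv` (cessation); `rsa_metrics.csv`,
#' `rsa_summary.csv`, `traces.json` (rsa); `pca_scores.csv`,
#' `pca_loadings.csv`, `variance_explained.csv`, `separation.csv`
#' (report); `run_manifest.json`.
#'
#' @param config config list or YAML path (see
#'   [validate_pipeline_config()]); `seed` is mandatory.
#' @param out_dir output directory (created if missing).
#' @return the run manifest, invisibly: a list with `config`, `seeds`,
#'   `files` (named MD5 digests), `timestamp`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- list()
  files <- character()
  stage <- function(name, fn) {
    seeds[[name]] <<- stage_seed(cfg$seed, name)
    tryCatch(fn(seeds[[name]]),
             error = function(e) {
               stop(sprintf("pipeline stage '%s' failed: %s", name,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  effect <- do.call(growth_effect_params, cfg$effect)

  # --- simulate -------------------------------------------------------
  panel <- stage("simulate", function(s) {
    pc <- panel_config(
      n_spring = cfg$panel$n_spring, n_winter = cfg$panel$n_winter,
      treatments = unlist(cfg$panel$treatments),
      replicates_per_condition = cfg$panel$replicates_per_condition,
      efficient_fraction = cfg$panel$efficient_fraction,
      effect = effect, noise_cv = cfg$panel$noise_cv, seed = s
    )
    generate_panel(pc)
  })
  files["manifest.csv"] <- .write_stage_csv(panel$manifest, out_dir,
                                            "manifest.csv")
  files["measurements.csv"] <- .write_stage_csv(panel$measurements, out_dir,
                                                "measurements.csv")
  files["ground_truth.csv"] <- .write_stage_csv(panel$ground_truth, out_dir,
                                                "ground_truth.csv")

  # --- extract (rendered images -> trait table) -----------------------
  traits <- stage("extract", function(s) {
    set.seed(s)
    n_img <- cfg$images$n_images
    imgs <- lapply(seq_len(n_img), function(i) {
      render_plant_image(cfg$images$shape,
                         size = cfg$images$size * (0.7 + 0.1 * i),
                         canvas_px = cfg$images$canvas_px)
    })
    for (i in seq_len(n_img)) {
      write_mask_png(imgs[[i]]$mask,
                     file.path(out_dir, sprintf("mask_%02d.png", i)))
      write_color_png(imgs[[i]]$color,
                      file.path(out_dir, sprintf("color_%02d.png", i)))
    }
    tbl <- tibble::tibble(
      plant_id = sprintf("img_plant_%02d", seq_len(n_img)),
      das = rep(13L, n_img),
      mask = lapply(imgs, `[[`, "mask"),
      color = lapply(imgs, `[[`, "color")
    )
    assemble_feature_table(tbl)
  })
  files["traits.csv"] <- .write_stage_csv(traits, out_dir, "traits.csv")

  # --- score ----------------------------------------------------------
  scored <- stage("score", function(s) {
    rank_panel(panel$measurements, threshold = cfg$scoring$threshold,
               min_n = cfg$scoring$min_n)
  })
  files["bei_results.csv"] <- .write_stage_csv(scored$results, out_dir,
                                               "bei_results.csv")

  # --- rgr (phenotyping-facility emulation on a panel subset) ---------
  pheno_acc <- panel$manifest$accession_id[
    seq_len(min(cfg$phenotyping$n_accessions, nrow(panel$manifest)))]
  pheno_class <- panel$manifest$true_class[
    match(pheno_acc, panel$manifest$accession_id)]
  series_tbl <- stage("rgr_simulate", function(s) {
    rows <- list()
    k <- 0L
    for (ai in seq_along(pheno_acc)) {
      for (trt in intersect(unlist(cfg$panel$treatments), c("B0", "B1", "B2"))) {
        for (rep_i in seq_len(cfg$phenotyping$replicates)) {
          k <- k + 1L
          rows[[k]] <- simulate_growth_series(
            class = pheno_class[ai], treatment = trt, params = effect,
            seed = stage_seed(s, paste(pheno_acc[ai], trt, rep_i)),
            days = unlist(cfg$phenotyping$days),
            plant_id = sprintf("%s_%s_r%d", pheno_acc[ai], trt, rep_i),
            accession_id = pheno_acc[ai]
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  files["growth_series.csv"] <- .write_stage_csv(series_tbl, out_dir,
                                                 "growth_series.csv")
  rgr <- stage("rgr", function(s) {
    rgr_by_windows(series_tbl, windows = cfg$phenotyping$windows,
                   arrest_epsilon = cfg$phenotyping$arrest_epsilon)
  })
  files["rgr.csv"] <- .write_stage_csv(rgr$per_plant, out_dir, "rgr.csv")
  files["rgr_summary.csv"] <- .write_stage_csv(rgr$summary, out_dir,
                                               "rgr_summary.csv")

  # --- cessation ------------------------------------------------------
  ces_acc <- pheno_acc[seq_len(min(cfg$cessation$n_accessions,
                                   length(pheno_acc)))]
  ces_class <- pheno_class[match(ces_acc, pheno_acc)]
  slopes <- stage("cessation", function(s) {
    n_seedlings <- cfg$cessation$replicates *
      cfg$cessation$seedlings_per_replicate
    out <- list()
    depth_rows <- list()
    for (ai in seq_along(ces_acc)) {
      for (cond in c("sufficient", "deficient")) {
        tbl <- dplyr::bind_rows(lapply(seq_len(n_seedlings), function(j) {
          simulate_root_depth_series(
            class = ces_class[ai], condition = cond,
            seed = stage_seed(s, paste(ces_acc[ai], cond, j)),
            n_days = cfg$cessation$n_days,
            seedling_id = sprintf("%s_%s_s%02d", ces_acc[ai], cond, j),
            accession_id = ces_acc[ai]
          )
        }))
        depth_rows[[paste(ces_acc[ai], cond)]] <- tbl
        sr <- gain_slope_coefficient(tbl)
        out[[paste(ces_acc[ai], cond)]] <- tibble::tibble(
          accession_id = ces_acc[ai], condition = cond,
          n_seedlings = sr$n_seedlings,
          slope_coefficient = sr$slope_coefficient,
          slope_sd = sr$slope_sd,
          cessation_flag = sr$cessation_flag
        )
      }
    }
    files["root_depth.csv"] <<- .write_stage_csv(
      dplyr::bind_rows(depth_rows), out_dir, "root_depth.csv")
    dplyr::bind_rows(out)
  })
  files["slopes.csv"] <- .write_stage_csv(slopes, out_dir, "slopes.csv")

  # --- rsa ------------------------------------------------------------
  rsa <- stage("rsa", function(s) {
    conditions <- c("none", "B")
    traces <- list()
    metrics <- list()
    for (cult in c("IE_like", "E_like")) {
      for (cond in conditions) {
        for (p in seq_len(cfg$rsa$n_plants)) {
          # B deficiency prunes laterals in the inefficient cultivar
          n_lat <- if (cult == "IE_like" && cond == "B") {
            max(1L, round(cfg$rsa$n_laterals / 4))
          } else {
            cfg$rsa$n_laterals
          }
          id <- sprintf("%s_%s_p%d", cult, cond, p)
          tr <- simulate_root_trace(
            n_lat, cfg$rsa$pr_length_cm, cfg$rsa$lateral_length_cm,
            seed = stage_seed(s, id)
          )
          traces[[id]] <- tr
          m <- trace_metrics(tr, plant_id = id)
          m$cultivar <- cult
          m$condition <- cond
          metrics[[id]] <- m
        }
      }
    }
    files["traces.json"] <<- write_traces_json(traces,
                                               file.path(out_dir,
                                                         "traces.json"))
    dplyr::bind_rows(metrics)
  })
  files["rsa_metrics.csv"] <- .write_stage_csv(rsa, out_dir,
                                               "rsa_metrics.csv")
  files["rsa_summary.csv"] <- .write_stage_csv(
    rsa_summary(rsa), out_dir, "rsa_summary.csv")

  # --- report (replicate means -> PCA -> separation) ------------------
  report <- stage("report", function(s) {
    long <- series_tbl
    long$replicate <- sub(".*_r", "", long$plant_id)
    trait_tbl <- tibble::tibble(
      cultivar = long$accession_id, treatment = long$treatment,
      day = long$das, replicate = long$replicate,
      projected_area_px = long$area, border_length_px = long$border_length
    )
    rm <- replicate_mean_matrix(trait_tbl)
    pca <- pca_traits(rm$matrix, standardize = TRUE)
    sep <- vapply(unique(rm$meta$cultivar), function(cv) {
      rows <- rm$meta$cultivar == cv
      treatment_separation_index(pca$scores[rows, , drop = FALSE],
                                 rm$meta$treatment[rows])
    }, numeric(1))
    list(pca = pca, meta = rm$meta,
         separation = tibble::tibble(cultivar = unique(rm$meta$cultivar),
                                     separation = sep))
  })
  files["pca_scores.csv"] <- .write_stage_csv(
    cbind(report$meta, as.data.frame(report$pca$scores)),
    out_dir, "pca_scores.csv")
  files["pca_loadings.csv"] <- .write_stage_csv(
    data.frame(trait = rownames(report$pca$loadings),
               as.data.frame(report$pca$loadings)),
    out_dir, "pca_loadings.csv")
  files["variance_explained.csv"] <- .write_stage_csv(
    data.frame(component = seq_along(report$pca$variance_explained),
               variance_explained = report$pca$variance_explained),
    out_dir, "variance_explained.csv")
  files["separation.csv"] <- .write_stage_csv(report$separation, out_dir,
                                              "separation.csv")

  # image files into the digest list too
  pngs <- list.files(out_dir, pattern = "\\.png$", full.names = FALSE)
  for (p in pngs) files[p] <- file.path(out_dir, p)

  digests <- vapply(files, function(p) unname(tools::md5sum(p)),
                    character(1))
  manifest <- list(
    config = cfg,
    seeds = seeds,
    files = as.list(digests),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
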