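#' Write a synthetic scene to disk
#'
#' Writes the ground-truth table as CSV and, when the tiff package is
#' available, the image (32-bit float TIFF) and the label mask (16-bit
#' TIFF).
#'
#' @param scene A `polarity_scene`.
#' @param dir Output directory (created if needed).
#' @param basename File name stem.
#' @return Invisible character vector of files written.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  truth_path <- file.path(dir, paste0(basename, "_truth.csv"))
  write.csv(scene$truth, truth_path, row.names = FALSE)
  files <- truth_path
  if (requireNamespace("tiff", quietly = TRUE)) {
    img_path <- file.path(dir, paste0(basename, "_image.tif"))
    mask_path <- file.path(dir, paste0(basename, "_masks.tif"))
    tiff::writeTIFF(scene$image / max(scene$image), img_path,
                    bits.per.sample = 32)
    tiff::writeTIFF(scene$masks / 65535, mask_path, bits.per.sample = 16)
    files <- c(files, img_path, mask_path)
  }
  invisible(files)
}

#' Read an image and label-mask TIFF pair
#'
#' Counterpart of [write_scene()]: reads a grayscale image and an integer
#' label mask from TIFF files, ready for [quantify_scene()].
#'
#' @param image_path Grayscale TIFF (any bit depth; values are rescaled by
#'   `image_scale`).
#' @param masks_path 16-bit label TIFF as written by [write_scene()].
#' @param image_scale Factor multiplying the raw image values (TIFF readers
#'   return intensities in `[0, 1]`).
#' @return List with `image` (numeric matrix) and `masks` (integer matrix).
#' @export
read_scene_images <- function(image_path, masks_path, image_scale = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    abort("the tiff package is required to read TIFF files")
  img <- tiff::readTIFF(image_path) * image_scale
  masks <- matrix(as.integer(round(tiff::readTIFF(masks_path) * 65535)),
                  nrow = nrow(img))
  list(image = img, masks = masks)
}

#' Compare quantified records against planted scene truth
#'
#' Matches each cell's geometric poles between the ground-truth table and
#' the quantification record by distance, and reports, for every planted
#' pole with fraction at least `min_fraction`, whether a spot was detected
#' there and the measured polar fraction.
#'
#' @param scene A `polarity_scene`.
#' @param records Output of [quantify_scene()] on that scene.
#' @param min_fraction Minimum planted polar fraction for inclusion.
#' @return Tibble: `cell_id`, `pole`, `planted`, `measured`, `detected`.
#' @export
evaluate_scene_recovery <- function(scene, records, min_fraction = 0.05) {
  joined <- dplyr::inner_join(records, scene$truth, by = "cell_id",
                              suffix = c("", "_true"))
  rows <- purrr::pmap(joined, function(...) {
    r <- list(...)
    # align truth poles to record poles by distance
    d_straight <- (r$pole1_x - r$pole1_x_true)^2 +
      (r$pole1_y - r$pole1_y_true)^2 +
      (r$pole2_x - r$pole2_x_true)^2 + (r$pole2_y - r$pole2_y_true)^2
    d_crossed <- (r$pole1_x - r$pole2_x_true)^2 +
      (r$pole1_y - r$pole2_y_true)^2 +
      (r$pole2_x - r$pole1_x_true)^2 + (r$pole2_y - r$pole1_y_true)^2
    planted <- if (d_straight <= d_crossed) c(r$p1_true, r$p2_true) else
      c(r$p2_true, r$p1_true)
    tibble(cell_id = r$cell_id, pole = 1:2, planted = planted,
           measured = c(r$p_pole1, r$p_pole2),
           detected = c(r$p_pole1, r$p_pole2) > 0)
  })
  out <- dplyr::bind_rows(rows)
  out[out$planted >= min_fraction, ]
}

pipeline_stages <- c("snapshot", "quantify", "summarize", "timelapse",
                     "track", "induction", "fit", "simulate")

#' Run an end-to-end analysis pipeline
#'
#' Executes a list of stages from a single configuration, with one global
#' seed from which per-stage seeds are derived, writing tabular outputs to
#' `out_dir` and returning a manifest (stage outputs, their MD5 checksums,
#' seeds, package version). Identical config plus seed yields byte-identical
#' outputs.
#'
#' Available stages and their config blocks:
#' * `snapshot`: [scene_config()] arguments; writes `truth.csv`.
#' * `quantify`: [filter_config()] arguments; quantifies the snapshot
#'   scene; writes `records.csv`.
#' * `summarize`: summarises the records; writes `summary.json`.
#' * `timelapse`: [timelapse_config()] arguments; writes
#'   `timelapse_truth.csv`.
#' * `track`: tracks the time-lapse truth; writes `tracks.csv` and
#'   `events.csv`.
#' * `induction`: [induction_config()] arguments; writes `induction.csv`.
#' * `fit`: [fit_hierarchical()] arguments (default: packaged strain
#'   means); writes `params.json` and `fit_residuals.csv`.
#' * `simulate`: [simulate_polarity()] on the fitted (or default)
#'   parameters; writes `trajectory.csv`.
#'
#' @param config List with elements `stages` (character vector), optional
#'   per-stage blocks (lists of arguments), `seed` (integer) and `out_dir`.
#' @return List of class `pipeline_manifest` with `status` (0 on success),
#'   `stages`, `outputs`, `checksums`, `seed`, `version`.
#' @export
#' @examples
#' run_pipeline(list(stages = character(0), out_dir = tempfile()))$status
run_pipeline <- function(config) {
  if (!is.list(config)) abort("config must be a list", class = "mx_config_error")
  stages <- config$stages %||% character(0)
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad))
    abort(paste("unknown stage(s):", paste(bad, collapse = ", ")),
          class = "mx_config_error")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  outputs <- list()
  env <- new.env()
  csv <- function(x, name) {
    path <- file.path(out_dir, name)
    write.csv(x, path, row.names = FALSE)
    path
  }
  for (stage in stages) {
    blk <- config[[stage]] %||% list()
    s <- derive_seed(seed, stage)
    outputs[[stage]] <- switch(
      stage,
      snapshot = {
        cfg <- do.call(scene_config, c(blk, list(rng_seed = s)))
        env$scene <- generate_snapshot_scene(cfg)
        csv(env$scene$truth, "truth.csv")
      },
      quantify = {
        if (is.null(env$scene)) abort("quantify requires the snapshot stage")
        fcfg <- do.call(filter_config, blk)
        env$records <- quantify_scene(env$scene, config = fcfg)
        csv(env$records, "records.csv")
      },
      summarize = {
        if (is.null(env$records)) abort("summarize requires quantify")
        sm <- summarize_strain(env$records)
        path <- file.path(out_dir, "summary.json")
        jsonlite::write_json(glance(sm), path, auto_unbox = TRUE, digits = NA)
        path
      },
      timelapse = {
        scfg <- do.call(scene_config, config$snapshot %||% list())
        dcfg <- do.call(timelapse_config, blk)
        env$timelapse <- generate_timelapse(scfg, dcfg, seed = s)
        csv(env$timelapse$truth, "timelapse_truth.csv")
      },
      track = {
        if (is.null(env$timelapse)) abort("track requires the timelapse stage")
        tcfg <- do.call(tracking_config, blk)
        env$tracks <- track_cells(env$timelapse$truth, tcfg)
        inv <- inversion_probability(env$tracks)
        c(csv(env$tracks, "tracks.csv"),
          csv(inv$events, "events.csv"))
      },
      induction = {
        icfg <- do.call(induction_config, blk)
        rec <- generate_induction_series(icfg, per_cell = TRUE, seed = s)
        csv(rec, "induction.csv")
      },
      fit = {
        tab <- if (!is.null(blk$strain_table)) {
          build_strain_table(blk$strain_table)
        } else {
          strain_means()
        }
        args <- blk[setdiff(names(blk), "strain_table")]
        env$fit <- do.call(fit_hierarchical,
                           c(list(strain_table = tab, seed = s), args))
        path <- file.path(out_dir, "params.json")
        jsonlite::write_json(unclass(env$fit$params), path,
                             auto_unbox = TRUE, digits = NA)
        c(path, csv(env$fit$residuals, "fit_residuals.csv"))
      },
      simulate = {
        p <- if (!is.null(env$fit)) env$fit$params else
          do.call(polarity_parameters, blk$params %||% list())
        traj <- simulate_polarity(p, t_end = blk$t_end %||% 1000)
        csv(traj, "trajectory.csv")
      })
  }
  files <- unlist(outputs, use.names = FALSE)
  manifest <- list(status = 0L, stages = stages,
                   outputs = outputs,
                   checksums = if (length(files))
                     as.list(tools::md5sum(files)) else list(),
                   seed = seed,
                   version = as.character(utils::packageVersion("mxpolarity")))
  class(manifest) <- "pipeline_manifest"
  manifest
}

#' Recompute the benchmark quantities of the package
#'
#' Runs the fitting benchmark (model fitted to the packaged strain means;
#' wild-type and mutant steady-state polar fractions) and the property
#' suite (LoG kernel closed form, synthetic image recovery, tracking
#' estimator, RomR dominance) from scratch and returns one row per
#' quantity with its value and runtime.
#'
#' @param seed Integer seed for every stochastic component.
#' @param n_starts Restarts for the fitting stage.
#' @param out_dir Optional directory for a JSON copy of the report.
#' @return Tibble with columns `target`, `value`, `n`, `seconds`.
#' @export
reproduce_benchmarks <- function(seed = 1, n_starts = 50, out_dir = NULL) {
  rows <- list()
  clock <- function(name, n, expr) {
    t0 <- Sys.time()
    val <- force(expr)
    rows[[name]] <<- tibble(target = name, value = unname(val), n = n,
                            seconds = as.numeric(Sys.time() - t0,
                                                 units = "secs"))
    val
  }

  tab <- strain_means()
  t0 <- Sys.time()
  fit <- fit_hierarchical(tab, n_starts = n_starts, seed = seed)
  fit_secs <- as.numeric(Sys.time() - t0, units = "secs")
  wt <- steady_state(fit$params, polarity_condition("wt"))$state
  dadb <- steady_state(fit$params, polarity_condition("dAdB"))$state
  da <- steady_state(fit$params, polarity_condition("dA"))$state
  n_rows <- nrow(tab)
  rows[["wt_romr_total_pct"]] <- tibble(
    target = "wt_romr_total_pct", value = 100 * (wt[["R1"]] + wt[["R2"]]),
    n = n_rows, seconds = fit_secs)
  clock("wt_mglb_total_pct", n_rows, 100 * (wt[["B1"]] + wt[["B2"]]))
  clock("wt_mgla_total_pct", n_rows, 100 * (wt[["A1"]] + wt[["A2"]]))
  clock("wt_omega_r", n_rows, polar_asymmetry(wt[["R1"]], wt[["R2"]]))
  clock("romr_only_total_pct", n_rows,
        100 * (dadb[["R1"]] + dadb[["R2"]]))
  clock("da_romr_total_pct", n_rows, 100 * (da[["R1"]] + da[["R2"]]))

  clock("log_kernel_center", 81, log_kernel()[5, 5])
  clock("dominance_threshold_pct", 1,
        100 * dominance_threshold(fit$params, b0 = 0.01)$threshold)

  sc <- generate_snapshot_scene(
    scene_config(image_width = 1024, image_height = 1024, n_cells = 100,
                 rng_seed = derive_seed(seed, "scene")))
  rec <- quantify_scene(sc)
  rcv <- evaluate_scene_recovery(sc, rec)
  clock("detector_recall", nrow(rcv), mean(rcv$detected))
  clock("polar_fraction_rmse", nrow(rcv),
        sqrt(mean((rcv$measured - rcv$planted)^2)))

  tl <- generate_timelapse(
    scene_config(n_cells = 25, image_width = 900, image_height = 900),
    timelapse_config(n_frames = 25, inversion_prob = 0.2,
                     division_prob = 0, drift_sd = 0.5),
    seed = derive_seed(seed, "timelapse"))
  tr <- track_cells(tl$truth)
  clock("inversion_probability_q20", NA_integer_,
        inversion_probability(tr)$probability)

  report <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(out_dir, "benchmarks.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  attr(report, "fit") <- fit
  report
}
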