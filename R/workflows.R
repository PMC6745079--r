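#' Workflow entry points
#'
#' Thin, validated wrappers tying the modules into reproducible runs.
#' Each workflow validates its inputs fully before writing any output,
#' stamps outputs with provenance (package version, timestamp, seed and a
#' config hash), and prints floating-point values with 6 significant
#' digits. The same functions back the `uteq` command-line script shipped
#' in `inst/cli/`.
#'
#' @name uteq_workflows
NULL

pkg_version <- function() {
  as.character(utils::packageVersion("uteq"))
}

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

provenance <- function(config, seed = NULL) {
  list(package = "uteq", version = pkg_version(),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, config_hash = config_hash(config))
}

#' Calibrate and save a bias-correction model
#'
#' Simulates the noiseless bias grid, fits the degree-4 polynomial
#' correction and serializes it as JSON. The bias grid itself can be
#' exported as long-format CSV alongside.
#'
#' @param t2l Assumed slow-component T2* (ms).
#' @param schedule Schedule preset name or `echo_schedule`.
#' @param grid Grid preset name (see [grid_preset()]) or a list with
#'   `t2s` and `f_bw` axes.
#' @param out Output JSON path for the correction model.
#' @param grid_csv Optional CSV path for the bias grid.
#' @return The `correction_model`, invisibly.
#' @export
uteq_calibrate <- function(t2l = 20, schedule = "abbreviated",
                           grid = "clinical", out, grid_csv = NULL) {
  axes <- if (is.character(grid)) grid_preset(grid) else grid
  cfg <- list(command = "calibrate", t2l = t2l,
              schedule = as_schedule(schedule)$name,
              t2s_axis = axes$t2s, fbw_axis = axes$f_bw)
  bg <- simulate_bias_grid(axes$t2s, axes$f_bw, t2l = t2l,
                           schedule = schedule)
  model <- fit_correction(bg)
  model$provenance <- provenance(cfg)
  write_correction(model, out)
  if (!is.null(grid_csv)) {
    utils::write.csv(format(as.data.frame(bg), digits = 6), grid_csv,
                     row.names = FALSE, quote = FALSE)
  }
  s <- summarize_bias_grid(bg)
  message(sprintf(
    "calibrated at T2l* = %g ms; apparent-bias %%: t2s %.3g, f_bw %.3g",
    t2l, s$mean_abs_rel_bias_pct[1], s$mean_abs_rel_bias_pct[2]))
  invisible(model)
}

#' Fit a decay curve from a CSV of (te_ms, signal)
#'
#' @param csv Input CSV with columns `te_ms` and `signal`.
#' @param schedule Schedule preset name or object; decides the model
#'   ("abbreviated"-style schedules use the baseline-corrected fit, the
#'   "vte" ladder a mono-exponential long-T2* fit, "full" the
#'   bi-exponential fit).
#' @param correction Optional path to a correction-model JSON; when given
#'   (abbreviated fits only) corrected values are reported too.
#' @param out Optional output JSON path for the estimates.
#' @return A list of estimates, invisibly.
#' @export
uteq_fit <- function(csv, schedule = "abbreviated", correction = NULL,
                     out = NULL) {
  dat <- utils::read.csv(csv)
  if (!all(c("te_ms", "signal") %in% names(dat))) {
    stop("input CSV needs columns `te_ms` and `signal`", call. = FALSE)
  }
  sched <- as_schedule(schedule)
  curve <- decay_curve(dat$te_ms, dat$signal, sched)
  res <- if (sched$name == "vte" || length(sched$te2) == 0L) {
    list(model = "mono_exponential_t2l", fit = fit_t2l_monoexp(curve))
  } else if (sched$name == "full") {
    list(model = "bi_exponential", fit = unclass(fit_biexp(curve)))
  } else {
    app <- fit_abbreviated(curve)
    r <- list(model = "baseline_corrected_monoexp", fit = unclass(app))
    if (!is.null(correction)) {
      cm <- read_correction(correction)
      r$corrected <- unclass(apply_correction(app, cm))[
        c("t2s", "f_bw", "t2l_assumed", "method")]
    }
    r
  }
  res$provenance <- provenance(list(command = "fit", csv = csv,
                                    schedule = sched$name))
  if (!is.null(out)) {
    jsonlite::write_json(res, out, auto_unbox = TRUE, digits = 6)
  }
  invisible(res)
}

#' Run the SNR study workflow
#'
#' @param correction Path to a correction-model JSON (from
#'   [uteq_calibrate()]).
#' @param out Output CSV path (long format); a companion wide-format
#'   table is written next to it with suffix `_wide.csv`.
#' @param snr_levels,n_reps,seed Passed to [snr_study_config()].
#' @return The `snr_study_result`, invisibly.
#' @export
uteq_snr_study <- function(correction, out,
                           snr_levels = c(1000, 800, 600, 400, 200),
                           n_reps = 500, seed = 1L) {
  cm <- read_correction(correction)
  cfg <- snr_study_config(snr_levels = snr_levels, n_reps = n_reps,
                          seed = seed)
  res <- run_snr_study(cfg, cm)
  utils::write.csv(format(as.data.frame(res), digits = 6), out,
                   row.names = FALSE, quote = FALSE)
  sm <- summarize_snr_study(res)
  wide_path <- sub("\\.csv$", "_wide.csv", out)
  utils::write.csv(format(sm$wide, digits = 6), wide_path,
                   row.names = FALSE, quote = FALSE)
  message(paste(sm$text, collapse = "\n"))
  invisible(res)
}

#' Generate and save a synthetic phantom
#'
#' Writes per-echo NIfTI volumes, per-segment mask NIfTIs and a
#' ground-truth JSON into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param schedule Schedule preset name or object.
#' @param snr,seed Rendering noise level and seed.
#' @param spec A `phantom_spec`; defaults to [default_acl_phantom()].
#' @return The built phantom, invisibly.
#' @export
uteq_phantom <- function(out_dir, schedule = "abbreviated", snr = Inf,
                         seed = 1L, spec = NULL) {
  spec <- spec %||% default_acl_phantom(snr = snr, seed = seed)
  sched <- as_schedule(schedule)
  ph <- build_phantom(spec)
  vols <- render_echoes(ph, sched, snr = snr, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(vols)) {
    write_volume_nifti(vols[[i]],
                       file.path(out_dir, paste0(names(vols)[i], ".nii.gz")),
                       voxel_size = spec$voxel_size)
  }
  for (nm in names(ph$masks)) {
    write_mask_nifti(ph$masks[[nm]],
                     file.path(out_dir,
                               paste0("mask_", gsub("[^a-z0-9]+", "_", nm),
                                      ".nii.gz")))
  }
  truth <- lapply(spec$segments, function(s) {
    c(list(label = s$label, angle_deg = s$angle_deg %||% 0),
      unclass(s$params))
  })
  meta <- list(segments = truth, snr = snr, seed = seed,
               schedule = sched$name,
               provenance = provenance(list(command = "phantom",
                                            snr = snr, seed = seed),
                                       seed = seed))
  jsonlite::write_json(meta, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 6)
  invisible(ph)
}

#' ROI report workflow
#'
#' For each mask: ROI-mean curve, abbreviated fit, optional bias
#' correction, and orientation to B0; results are written as CSV.
#'
#' @param image_paths Character vector of per-echo NIfTI paths, ordered
#'   as the schedule's pooled echo times.
#' @param mask_paths Character vector of ROI mask NIfTI paths.
#' @param schedule Schedule preset name or object.
#' @param correction Optional correction-model JSON path.
#' @param out Output CSV path.
#' @param b0_axis B0 axis index for the masks.
#' @return Data.frame of the report, invisibly.
#' @export
uteq_roi_report <- function(image_paths, mask_paths,
                            schedule = "abbreviated", correction = NULL,
                            out = NULL, b0_axis = 3L) {
  sched <- as_schedule(schedule)
  vols <- lapply(image_paths, read_volume_nifti)
  cm <- if (!is.null(correction)) read_correction(correction)
  rows <- lapply(mask_paths, function(mp) {
    mask <- read_mask_nifti(mp, b0_axis = b0_axis,
                            label = sub("\\.nii(\\.gz)?$", "", basename(mp)))
    curve <- roi_mean_curve(vols, mask, sched)
    app <- fit_abbreviated(curve)
    ang <- tryCatch(angle_to_b0(mask), error = function(e) NA_real_)
    row <- data.frame(label = mask$label, n_voxels = n_voxels(mask),
                      t2s_app = app$t2s_app, f_bw_app = app$f_bw_app,
                      baseline = app$baseline, angle_to_b0 = ang,
                      flagged = app$flagged)
    if (!is.null(cm)) {
      corr <- suppressWarnings(apply_correction(app, cm))
      row$t2s_corrected <- corr$t2s
      row$f_bw_corrected <- corr$f_bw
    }
    row
  })
  rep <- do.call(rbind, rows)
  if (!is.null(out)) {
    utils::write.csv(format(rep, digits = 6), out, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(rep)
}

#' Command-line dispatcher
#'
#' Backs the `uteq` script in `inst/cli/`. Subcommands: `calibrate`,
#' `fit`, `snr-study`, `phantom`, `roi-report`. Arguments are `--key
#' value` pairs matching the corresponding workflow function's
#' parameters; list-valued arguments are comma-separated.
#'
#' @param argv Character vector of command-line arguments (excluding the
#'   program name).
#' @return Integer exit status (0 on success), invisibly.
#' @export
uteq_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: uteq <calibrate|fit|snr-study|phantom|roi-report> [--key value ...]",
    "       uteq --version", sep = "\n")
  if (length(argv) == 0L) { message(usage); return(invisible(1L)) }
  if (argv[1] == "--version") {
    cat("uteq", pkg_version(), "\n"); return(invisible(0L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  opts <- list()
  i <- 1L
  while (i <= length(rest)) {
    key <- rest[i]
    if (!startsWith(key, "--") || i == length(rest)) {
      message("malformed arguments near '", key, "'\n", usage)
      return(invisible(1L))
    }
    opts[[sub("^--", "", key)]] <- rest[i + 1L]
    i <- i + 2L
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  numv <- function(x) if (is.null(x)) NULL else
    as.numeric(strsplit(x, ",")[[1]])
  chrv <- function(x) if (is.null(x)) NULL else strsplit(x, ",")[[1]]
  status <- tryCatch({
    switch(cmd,
      "calibrate" = uteq_calibrate(
        t2l = num(opts$t2l) %||% 20,
        schedule = opts$schedule %||% "abbreviated",
        grid = opts$grid %||% "clinical",
        out = opts$out %||% stop("--out is required", call. = FALSE),
        grid_csv = opts[["grid-csv"]]),
      "fit" = uteq_fit(
        csv = opts$csv %||% stop("--csv is required", call. = FALSE),
        schedule = opts$schedule %||% "abbreviated",
        correction = opts$correction, out = opts$out),
      "snr-study" = uteq_snr_study(
        correction = opts$correction %||%
          stop("--correction is required", call. = FALSE),
        out = opts$out %||% stop("--out is required", call. = FALSE),
        snr_levels = numv(opts[["snr-levels"]]) %||%
          c(1000, 800, 600, 400, 200),
        n_reps = num(opts[["n-reps"]]) %||% 500,
        seed = as.integer(num(opts$seed) %||% 1)),
      "phantom" = uteq_phantom(
        out_dir = opts$out %||% stop("--out is required", call. = FALSE),
        schedule = opts$schedule %||% "abbreviated",
        snr = num(opts$snr) %||% Inf,
        seed = as.integer(num(opts$seed) %||% 1)),
      "roi-report" = uteq_roi_report(
        image_paths = chrv(opts$images) %||%
          stop("--images is required", call. = FALSE),
        mask_paths = chrv(opts$masks) %||%
          stop("--masks is required", call. = FALSE),
        schedule = opts$schedule %||% "abbreviated",
        correction = opts$correction, out = opts$out,
        b0_axis = as.integer(num(opts[["b0-axis"]]) %||% 3)),
      { message("unknown subcommand '", cmd, "'\n", usage)
        return(invisible(1L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
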