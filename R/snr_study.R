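#' Configuration for the SNR Monte-Carlo study
#'
#' Defines the comparison of the bias-corrected abbreviated estimator
#' against full bi-exponential fitting across SNR levels. SNR is defined
#' as the TE = 0 signal divided by the per-echo noise standard deviation;
#' noise is additive zero-mean Gaussian on each echo of the (already
#' ROI-averaged) curve. A Rician option models magnitude formation
#' explicitly instead.
#'
#' @param snr_levels SNR levels to simulate (default 1000, 800, 600, 400,
#'   200).
#' @param n_reps Noise replicates per grid node (>= 100 for reportable
#'   summaries; default 500).
#' @param seed Integer seed; every run is fully reproducible given it.
#' @param t2s_axis,fbw_axis Ground-truth grid (default 7 x 6 nodes over
#'   T2s* 0.5--2.0 ms, f_bw 0.70--0.95).
#' @param t2l Ground-truth slow-component T2* (ms), fixed at 20.
#' @param noise "gaussian" (default) or "rician".
#' @return An object of class `snr_study_config`.
#' @export
snr_study_config <- function(snr_levels = c(1000, 800, 600, 400, 200),
                             n_reps = 500, seed = 1L,
                             t2s_axis = seq(0.5, 2.0, length.out = 7),
                             fbw_axis = seq(0.70, 0.95, length.out = 6),
                             t2l = 20,
                             noise = c("gaussian", "rician")) {
  noise <- match.arg(noise)
  stopifnot(all(snr_levels > 0), n_reps >= 1)
  if (n_reps < 100) {
    warning("n_reps < 100; summaries will be noisy", call. = FALSE)
  }
  structure(list(snr_levels = snr_levels, n_reps = as.integer(n_reps),
                 seed = as.integer(seed), t2s_axis = t2s_axis,
                 fbw_axis = fbw_axis, t2l = t2l, noise = noise),
            class = "snr_study_config")
}

add_noise <- function(y, sigma, kind) {
  if (kind == "gaussian") {
    pmax(y + stats::rnorm(length(y), 0, sigma), 1e-9)
  } else {
    # magnitude of complex signal with iid Gaussian noise per channel
    sqrt((y + stats::rnorm(length(y), 0, sigma))^2 +
         stats::rnorm(length(y), 0, sigma)^2)
  }
}

#' Run the SNR Monte-Carlo study
#'
#' For every grid node, replicate and SNR level: draws a noisy realization
#' of the bi-exponential curve on each schedule, estimates parameters by
#' (a) the abbreviated fit followed by the calibrated bias correction and
#' (b) full bi-exponential fitting, and accumulates absolute percent
#' errors against ground truth. Divergent or bound-pinned fits are counted
#' and excluded from the summaries.
#'
#' @param config An `snr_study_config`.
#' @param correction A `correction_model` calibrated at the config's `t2l`
#'   on the abbreviated schedule.
#' @param abbreviated_schedule,full_schedule Echo schedules for the two
#'   arms.
#' @return An object of class `snr_study_result`: data.frame in long
#'   format with columns `snr`, `method`, `parameter`,
#'   `mean_abs_pct_error`, `sd_pct_error`, `n_used`, `n_excluded`;
#'   attribute `config`.
#' @export
run_snr_study <- function(config, correction,
                          abbreviated_schedule = "abbreviated",
                          full_schedule = "full") {
  stopifnot(inherits(config, "snr_study_config"))
  if (!inherits(correction, "correction_model")) {
    stop("a correction_model calibrated at T2l* = ", config$t2l,
         " ms is required", call. = FALSE)
  }
  if (!isTRUE(all.equal(correction$t2l_assumed, config$t2l))) {
    warning("correction was calibrated at T2l* = ",
            correction$t2l_assumed, " ms but the study simulates ",
            config$t2l, " ms", call. = FALSE)
  }
  ab <- as_schedule(abbreviated_schedule)
  fu <- as_schedule(full_schedule)
  te_ab <- c(ab$te1, ab$te2)
  n_te1 <- length(ab$te1)
  te_fu <- fu$all_tes
  nodes <- expand.grid(t2s = config$t2s_axis, f_bw = config$fbw_axis,
                       KEEP.OUT.ATTRS = FALSE)
  set.seed(config$seed)
  rows <- list()
  n_total <- nrow(nodes) * config$n_reps
  for (snr in config$snr_levels) {
    sigma <- 1 / snr  # S0 = 1 by construction
    ab_t2s <- ab_fbw <- fu_t2s <- fu_fbw <- rep(NA_real_, n_total)
    k <- 0L
    for (i in seq_len(nrow(nodes))) {
      tt <- nodes$t2s[i]; ff <- nodes$f_bw[i]
      y_ab0 <- biexp_eval(te_ab, 1, ff, tt, config$t2l)
      y_fu0 <- biexp_eval(te_fu, 1, ff, tt, config$t2l)
      for (r in seq_len(config$n_reps)) {
        k <- k + 1L
        y_ab <- add_noise(y_ab0, sigma, config$noise)
        b <- mean(y_ab[-seq_len(n_te1)])
        fit_ab <- tryCatch(fit_abbrev_core(te_ab[seq_len(n_te1)],
                                           y_ab[seq_len(n_te1)], b),
                           error = function(e) NULL)
        if (!is.null(fit_ab) && !fit_ab$at_bound) {
          corr <- suppressWarnings(apply_correction(
            list(t2s_app = fit_ab$t2s_app, f_bw_app = fit_ab$f_bw_app),
            correction))
          ab_t2s[k] <- abs(corr$t2s - tt) / tt * 100
          ab_fbw[k] <- abs(corr$f_bw - ff) / ff * 100
        }
        y_fu <- add_noise(y_fu0, sigma, config$noise)
        fit_fu <- tryCatch(
          fit_biexp(decay_curve(te_fu, y_fu)),
          error = function(e) NULL)
        if (!is.null(fit_fu) && !fit_fu$flagged) {
          fu_t2s[k] <- abs(fit_fu$t2s - tt) / tt * 100
          fu_fbw[k] <- abs(fit_fu$f_bw - ff) / ff * 100
        }
      }
    }
    mk <- function(method, param, v) {
      ok <- !is.na(v)
      data.frame(snr = snr, method = method, parameter = param,
                 mean_abs_pct_error = mean(v[ok]),
                 sd_pct_error = stats::sd(v[ok]),
                 n_used = sum(ok), n_excluded = sum(!ok))
    }
    rows[[length(rows) + 1L]] <- rbind(
      mk("abbreviated_corrected", "t2s", ab_t2s),
      mk("abbreviated_corrected", "f_bw", ab_fbw),
      mk("full_biexp", "t2s", fu_t2s),
      mk("full_biexp", "f_bw", fu_fbw))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, config = config,
            class = c("snr_study_result", "data.frame"))
}

#' Summarize an SNR study as a wide table
#'
#' Reshapes the long-format result into the conventional report layout:
#' one row per SNR level, columns method x parameter, each cell
#' "mean +/- sd" of the absolute percent error.
#'
#' @param result An `snr_study_result`.
#' @param digits Significant digits for the formatted cells.
#' @return List with `wide` (numeric data.frame of means), `formatted`
#'   (character data.frame "mean +/- sd"), and `text` (a printable
#'   markdown-style table, one string per line).
#' @export
summarize_snr_study <- function(result, digits = 3) {
  stopifnot(inherits(result, "snr_study_result"))
  snrs <- sort(unique(result$snr), decreasing = TRUE)
  combos <- expand.grid(method = c("abbreviated_corrected", "full_biexp"),
                        parameter = c("f_bw", "t2s"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  combos <- combos[order(combos$method), ]
  wide <- data.frame(snr = snrs)
  fmt <- data.frame(snr = snrs)
  for (k in seq_len(nrow(combos))) {
    col <- paste(combos$method[k], combos$parameter[k], sep = ".")
    m <- s <- numeric(length(snrs))
    for (j in seq_along(snrs)) {
      row <- result[result$snr == snrs[j] &
                    result$method == combos$method[k] &
                    result$parameter == combos$parameter[k], ]
      m[j] <- row$mean_abs_pct_error
      s[j] <- row$sd_pct_error
    }
    wide[[col]] <- m
    fmt[[col]] <- sprintf("%s ± %s", signif(m, digits),
                          signif(s, digits))
  }
  header <- paste(c("SNR", names(fmt)[-1]), collapse = " | ")
  sep <- paste(rep("---", ncol(fmt)), collapse = " | ")
  body <- apply(fmt, 1, paste, collapse = " | ")
  list(wide = wide, formatted = fmt, text = c(header, sep, unname(body)))
}
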