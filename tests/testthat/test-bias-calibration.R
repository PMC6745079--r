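# A shared coarse clinical calibration used by several tests (31 x 21
# nodes keeps the whole file fast; summary values change by < 0.05 pp
# against the 61 x 41 default).
clinical_grid_31x21 <- simulate_bias_grid(
  seq(0.5, 2, length.out = 31), seq(0.75, 0.95, length.out = 21))
clinical_model <- fit_correction(clinical_grid_31x21)

test_that("bias grid stores apparent estimates and relative biases consistently", {
  bg <- clinical_grid_31x21
  expect_equal(nrow(bg), 31 * 21)
  expect_equal(bg$rel_bias_t2s,
               (bg$t2s_app - bg$t2s_true) / bg$t2s_true)
  expect_equal(bg$rel_bias_fbw,
               (bg$fbw_app - bg$fbw_true) / bg$fbw_true)
  expect_equal(attr(bg, "n_failed"), 0L)
  expect_equal(attr(bg, "t2l"), 20)
})

test_that("clinical-grid biases are small; low-f_bw biases are large", {
  s <- summarize_bias_grid(clinical_grid_31x21)
  expect_lt(s$mean_abs_rel_bias_pct[s$parameter == "t2s"], 5)
  expect_lt(s$mean_abs_rel_bias_pct[s$parameter == "f_bw"], 5)
  lo <- simulate_bias_grid(seq(0.5, 2, length.out = 13),
                           seq(0.25, 0.75, length.out = 9))
  slo <- summarize_bias_grid(lo)
  expect_gt(slo$mean_abs_rel_bias_pct[slo$parameter == "t2s"], 10)
  expect_gt(slo$mean_abs_rel_bias_pct[slo$parameter == "f_bw"], 30)
})

test_that("bias surface is smooth with a single sign change along t2s", {
  bg <- clinical_grid_31x21
  # within each f_bw row, t2s bias decreases from positive to negative
  # with at most one sign flip
  for (f in unique(bg$fbw_true)[c(1, 11, 21)]) {
    rb <- bg$rel_bias_t2s[bg$fbw_true == f][order(bg$t2s_true[bg$fbw_true == f])]
    flips <- sum(diff(sign(rb)) != 0)
    expect_lte(flips, 1)
  }
})

test_that("model-matched limit gives near-zero t2s bias", {
  # quasi-infinite slow pool (exact baseline) AND a short fast pool
  # (dead by TE2, e^-13 at 4 ms): the abbreviated model is then the true
  # model class, t2s_app is unbiased, and the apparent fraction equals
  # its analytic image 1 - (1 - f)/f under the printed parameterization
  bg <- simulate_bias_grid(0.3, 0.8, t2l = 1e6)
  expect_lt(abs(bg$rel_bias_t2s), 1e-4)
  expect_equal(bg$fbw_app, 1 - (1 - 0.8) / 0.8, tolerance = 1e-4)
})

test_that("correction fitted to a zero-bias grid is the identity", {
  # synthetic grid whose apparent values equal the truth exactly
  g <- expand.grid(t2s_true = seq(0.8, 1.6, length.out = 6),
                   fbw_true = seq(0.6, 0.9, length.out = 5))
  bg <- structure(
    data.frame(g, t2s_app = g$t2s_true, fbw_app = g$fbw_true,
               rel_bias_t2s = 0, rel_bias_fbw = 0, flagged = FALSE),
    t2l = 20, schedule = "abbreviated", n_flagged = 0L, n_failed = 0L,
    class = c("bias_grid", "data.frame"))
  m <- fit_correction(bg)
  pts <- list(t2s_app = c(0.9, 1.2, 1.5), f_bw_app = c(0.65, 0.75, 0.85))
  out <- apply_correction(pts, m)
  expect_equal(out$t2s, pts$t2s_app, tolerance = 1e-6)
  expect_equal(out$f_bw, pts$f_bw_app, tolerance = 1e-6)
})

test_that("polynomial coefficients match an independent QR solve", {
  bg <- clinical_grid_31x21
  # independent check on the package's own design: reconstruct the
  # predicted error surface at the nodes from the stored coefficients
  m <- clinical_model
  pred <- uteq:::poly4_design(bg$t2s_app, bg$fbw_app) %*% m$coeffs_t2s
  resid <- (bg$t2s_true - bg$t2s_app) - pred
  # OLS residuals must be orthogonal to the design columns
  D <- uteq:::poly4_design(bg$t2s_app, bg$fbw_app)
  expect_lt(max(abs(crossprod(D, resid))), 1e-7)
  # and the surface reproduces the tabulated error closely
  expect_lt(mean(abs(resid)), 5e-4)
})

test_that("calibrate-then-apply drives residual error near zero (round trip)", {
  bg <- clinical_grid_31x21
  out <- apply_correction(list(t2s_app = bg$t2s_app,
                               f_bw_app = bg$fbw_app), clinical_model)
  rel_t <- abs(out$t2s - bg$t2s_true) / bg$t2s_true
  rel_f <- abs(out$f_bw - bg$fbw_true) / bg$fbw_true
  expect_lt(mean(rel_t) * 100, 0.5)   # robust round-trip gate
  expect_lt(mean(rel_f) * 100, 0.5)
  # lookup-inversion mode is essentially exact at the calibration nodes
  lk <- apply_correction(list(t2s_app = bg$t2s_app,
                              f_bw_app = bg$fbw_app), clinical_model,
                         method = "lookup")
  expect_equal(lk$t2s, bg$t2s_true, tolerance = 1e-9)
  expect_equal(lk$f_bw, bg$fbw_true, tolerance = 1e-9)
})

test_that("correction preserves the ordering of apparent t2s on the clinical domain", {
  t2s_app <- seq(clinical_model$domain$t2s_app[1],
                 clinical_model$domain$t2s_app[2], length.out = 25)
  out <- apply_correction(list(t2s_app = t2s_app,
                               f_bw_app = rep(0.82, 25)), clinical_model)
  expect_true(all(diff(out$t2s) > 0))
})

test_that("calibration residuals shrink with grid density", {
  res_at <- function(n1, n2) {
    bg <- simulate_bias_grid(seq(0.5, 2, length.out = n1),
                             seq(0.75, 0.95, length.out = n2))
    m <- fit_correction(bg)
    # evaluate off-node on a fixed probe set
    probe <- simulate_bias_grid(seq(0.55, 1.95, length.out = 8),
                                seq(0.76, 0.94, length.out = 6))
    out <- apply_correction(list(t2s_app = probe$t2s_app,
                                 f_bw_app = probe$fbw_app), m)
    mean(abs(out$f_bw - probe$fbw_true) / probe$fbw_true)
  }
  expect_lte(res_at(31, 21), res_at(7, 5) * 1.05)
})

test_that("off-grid point is corrected close to truth (dense-grid oracle)", {
  cv <- make_abbrev_curve(0.88, 1.3)
  app <- fit_abbreviated(cv)
  dense <- fit_correction(simulate_bias_grid(
    seq(0.5, 2, length.out = 61), seq(0.75, 0.95, length.out = 41)))
  out <- apply_correction(app, dense)
  expect_equal(out$t2s, 1.3, tolerance = 1e-3)
  expect_equal(out$f_bw, 0.88, tolerance = 1e-3)
})

test_that("correction warns on extrapolation and clamps f_bw", {
  w <- testthat::capture_warnings(
    apply_correction(list(t2s_app = 4.5, f_bw_app = 0.85),
                     clinical_model))
  expect_true(any(grepl("extrapolat", w)))
  m0 <- clinical_model
  m0$coeffs_fbw[1] <- m0$coeffs_fbw[1] + 1  # push correction above 1
  expect_warning(
    out <- apply_correction(list(t2s_app = 1.2, f_bw_app = 0.9), m0),
    "clamped")
  expect_lte(out$f_bw, 1)
  expect_error(apply_correction(list(t2s_app = NaN, f_bw_app = 0.8),
                                clinical_model), "finite")
})

test_that("t2l mismatch degrades gracefully and vanishes at the calibrated value", {
  mm15 <- t2l_mismatch_study(clinical_model, 15, n_t2s = 16, n_fbw = 11)
  expect_lt(mm15$mean_abs_rel_err_pct[mm15$parameter == "t2s"], 2.5)
  expect_lt(mm15$mean_abs_rel_err_pct[mm15$parameter == "f_bw"], 2.5)
  mm20 <- t2l_mismatch_study(clinical_model, 20, n_t2s = 16, n_fbw = 11)
  # no mismatch: residuals collapse to the self-calibration level
  expect_lt(mm20$mean_abs_rel_err_pct[mm20$parameter == "t2s"], 0.1)
  expect_lt(mm20$mean_abs_rel_err_pct[mm20$parameter == "f_bw"], 0.1)
  expect_gt(mm15$mean_abs_rel_err_pct[1], mm20$mean_abs_rel_err_pct[1])
})

test_that("correction model survives a JSON round trip", {
  f <- tempfile(fileext = ".json")
  write_correction(clinical_model, f)
  m2 <- read_correction(f)
  expect_equal(unname(m2$coeffs_t2s), unname(clinical_model$coeffs_t2s),
               tolerance = 1e-12)
  expect_equal(m2$t2l_assumed, 20)
  out1 <- apply_correction(list(t2s_app = 1.1, f_bw_app = 0.85),
                           clinical_model)
  out2 <- apply_correction(list(t2s_app = 1.1, f_bw_app = 0.85), m2)
  expect_equal(out2$t2s, out1$t2s, tolerance = 1e-10)
  unlink(f)
})
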