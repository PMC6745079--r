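#' Ground-truth bicomponent tissue parameters
#'
#' Container for the four parameters of the bi-exponential magnitude decay
#' model: initial signal `s0` (arbitrary units), bound-water fraction
#' `f_bw` (the fraction of the TE = 0 signal contributed by the fast-decay
#' collagen-bound water pool), fast-component `t2s` and slow-component
#' `t2l` relaxation times (ms).
#'
#' @param s0 Initial signal, > 0.
#' @param f_bw Bound-water signal fraction, in (0, 1).
#' @param t2s Fast-component T2* (ms), 0 < t2s < t2l.
#' @param t2l Slow-component T2* (ms).
#' @return An object of class `tissue_params`.
#' @examples
#' tissue_params(1, 0.85, 1.4, 20)
#' @export
tissue_params <- function(s0 = 1, f_bw, t2s, t2l = 20) {
  stopifnot(is.numeric(s0), is.numeric(f_bw), is.numeric(t2s),
            is.numeric(t2l))
  if (!(s0 > 0)) stop("`s0` must be > 0", call. = FALSE)
  if (!(f_bw > 0 && f_bw < 1)) {
    stop("`f_bw` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(t2s > 0 && t2s < t2l)) {
    stop("need 0 < t2s < t2l", call. = FALSE)
  }
  structure(list(s0 = s0, f_bw = f_bw, t2s = t2s, t2l = t2l),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> S0 = %g, f_bw = %g, T2s* = %g ms, T2l* = %g ms\n",
              x$s0, x$f_bw, x$t2s, x$t2l))
  invisible(x)
}

#' Bi-exponential UTE signal model
#'
#' Magnitude signal of a two-pool tissue at echo time `te`:
#' \deqn{S(TE) = S_0 [ f_{bw} e^{-TE/T2s^*} + (1 - f_{bw}) e^{-TE/T2l^*} ]}
#' The fast pool is collagen-bound water (T2* of a few hundred
#' microseconds to ~2 ms), the slow pool free water (T2* of tens of ms).
#'
#' @param params A `tissue_params` object.
#' @param te Echo time(s), ms, >= 0. Vectorized.
#' @return Signal value(s), same length as `te`.
#' @examples
#' p <- tissue_params(1, 0.8, 1, 20)
#' biexp_signal(p, c(0, 0.5, 4))
#' @export
biexp_signal <- function(params, te) {
  stopifnot(inherits(params, "tissue_params"))
  if (any(!is.finite(te)) || any(te < 0)) {
    stop("`te` must be finite and >= 0", call. = FALSE)
  }
  params$s0 * (params$f_bw * exp(-te / params$t2s) +
               (1 - params$f_bw) * exp(-te / params$t2l))
}

# Non-validating vectorized kernel used in inner simulation loops.
biexp_eval <- function(te, s0, f_bw, t2s, t2l) {
  s0 * (f_bw * exp(-te / t2s) + (1 - f_bw) * exp(-te / t2l))
}

#' Baseline-corrected mono-exponential signal model
#'
#' Forward model of the abbreviated estimator. Over the sub-millisecond TE1
#' echoes the slow pool decays by only a few percent, so its contribution
#' is treated as a constant baseline (measured at the TE2 echoes) and the
#' decay is attributed entirely to the fast pool:
#' \deqn{S(TE) = \frac{baseline}{1 - f_{bw,app}} e^{-TE/T2s_{app}^*} + baseline}
#' The apparent bound-water fraction parameterizes the amplitude as
#' \eqn{A = baseline / (1 - f_{bw,app})}, equivalently
#' \eqn{f_{bw,app} = 1 - baseline / A}.
#'
#' @param t2s_app Apparent fast-component T2* (ms), > 0.
#' @param f_bw_app Apparent bound-water fraction, in (0, 1).
#' @param baseline Constant baseline signal, >= 0.
#' @param te Echo time(s), ms, >= 0. Vectorized.
#' @return Signal value(s).
#' @examples
#' abbreviated_signal(1.4, 0.85, 0.12, c(0.1, 0.27, 0.5))
#' @export
abbreviated_signal <- function(t2s_app, f_bw_app, baseline, te) {
  if (!(f_bw_app > 0 && f_bw_app < 1)) {
    stop("`f_bw_app` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!(t2s_app > 0)) stop("`t2s_app` must be > 0", call. = FALSE)
  if (!(baseline >= 0)) stop("`baseline` must be >= 0", call. = FALSE)
  if (any(!is.finite(te)) || any(te < 0)) {
    stop("`te` must be finite and >= 0", call. = FALSE)
  }
  baseline / (1 - f_bw_app) * exp(-te / t2s_app) + baseline
}
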