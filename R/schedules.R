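#' Construct an echo schedule
#'
#' An echo schedule partitions the echo times of a multi-echo UTE protocol
#' into the sub-millisecond TE1 set, used to fit the fast-decay component,
#' and the TE2 set (>= ~4 ms), used to estimate the constant baseline
#' contributed by the slow-decay component. Protocols that sample the decay
#' with a single ladder of echoes (e.g. a variable-TE gradient-echo scan for
#' long-T2* estimation) use only `te1` and leave `te2` empty.
#'
#' @param name Label for the schedule.
#' @param te1 Numeric vector of echo times (ms) used for fitting, strictly
#'   ascending, all positive.
#' @param te2 Numeric vector of echo times (ms) used for baseline
#'   estimation, strictly ascending, all positive. May be empty.
#' @return An object of class `echo_schedule` with fields `name`, `te1`,
#'   `te2` and `all_tes` (the pooled echo times, ascending).
#' @examples
#' sched <- echo_schedule("abbreviated", c(0.1, 0.27, 0.5), c(4, 5, 6))
#' sched$all_tes
#' @export
echo_schedule <- function(name, te1, te2 = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1L)
  te1 <- as.numeric(te1)
  te2 <- as.numeric(te2)
  if (length(te1) == 0L) {
    stop("`te1` must contain at least one echo time", call. = FALSE)
  }
  if (any(!is.finite(te1)) || any(te1 <= 0)) {
    stop("all TE1 echo times must be finite and > 0", call. = FALSE)
  }
  if (is.unsorted(te1, strictly = TRUE)) {
    stop("`te1` must be strictly ascending", call. = FALSE)
  }
  if (length(te2) > 0L) {
    if (any(!is.finite(te2)) || any(te2 <= 0)) {
      stop("all TE2 echo times must be finite and > 0", call. = FALSE)
    }
    if (is.unsorted(te2, strictly = TRUE)) {
      stop("`te2` must be strictly ascending", call. = FALSE)
    }
  }
  structure(
    list(name = name, te1 = te1, te2 = te2,
         all_tes = sort(c(te1, te2))),
    class = "echo_schedule"
  )
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat("<echo_schedule> ", x$name, "\n", sep = "")
  cat("  TE1 (fit set, ms):      ", paste(x$te1, collapse = ", "), "\n")
  if (length(x$te2)) {
    cat("  TE2 (baseline set, ms): ", paste(x$te2, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standard UTE echo schedules
#'
#' The three acquisition protocols supported out of the box:
#' \describe{
#'   \item{abbreviated}{three double-echo UTE scans, TE1/TE2 pairs
#'     0.1/4.0, 0.27/5.0 and 0.5/6.0 ms; clinically deployable in under
#'     10 minutes. TE1 echoes fit the fast component, TE2 echoes give the
#'     baseline.}
#'   \item{full}{five double-echo UTE scans (TE1/TE2 of 0.1/4.0, 0.27/7.0,
#'     0.5/10.0, 1.0/14.0, 2.0/20.0 ms) sampling the whole decay for
#'     conventional bi-exponential fitting. The TE1/TE2 split is retained
#'     for bookkeeping; bi-exponential fits use all ten echoes.}
#'   \item{vte}{a variable-TE Cartesian gradient-echo ladder
#'     (0.88, 3.24, 5.37, 7.5, 10, 13, 19 ms) used to estimate the long
#'     T2* with a mono-exponential fit; no baseline set.}
#' }
#'
#' @return A named list of three `echo_schedule` objects.
#' @export
standard_schedules <- function() {
  list(
    abbreviated = echo_schedule("abbreviated",
                                te1 = c(0.1, 0.27, 0.5),
                                te2 = c(4.0, 5.0, 6.0)),
    full = echo_schedule("full",
                         te1 = c(0.1, 0.27, 0.5, 1.0, 2.0),
                         te2 = c(4.0, 7.0, 10.0, 14.0, 20.0)),
    vte = echo_schedule("vte",
                        te1 = c(0.88, 3.24, 5.37, 7.5, 10, 13, 19))
  )
}

#' Look up a standard schedule by name, or pass one through
#'
#' @param schedule Either an `echo_schedule` or one of "abbreviated",
#'   "full", "vte".
#' @return An `echo_schedule`.
#' @keywords internal
as_schedule <- function(schedule) {
  if (inherits(schedule, "echo_schedule")) return(schedule)
  if (is.character(schedule) && length(schedule) == 1L) {
    std <- standard_schedules()
    if (schedule %in% names(std)) return(std[[schedule]])
    stop("unknown schedule name: ", schedule, call. = FALSE)
  }
  stop("`schedule` must be an echo_schedule or a preset name", call. = FALSE)
}

#' Read an echo schedule from a config list
#'
#' Config files (YAML/JSON) specify schedules as lists of ms values under
#' keys `te1` and `te2`, or reference a preset by name.
#'
#' @param x A list with elements `te1` and optionally `te2` and `name`, or
#'   a single preset name string.
#' @return An `echo_schedule`.
#' @export
schedule_from_config <- function(x) {
  if (is.character(x)) return(as_schedule(x))
  if (!is.list(x) || is.null(x$te1)) {
    stop("schedule config must be a preset name or a list with `te1`",
         call. = FALSE)
  }
  echo_schedule(name = if (is.null(x$name)) "custom" else x$name,
                te1 = unlist(x$te1),
                te2 = if (is.null(x$te2)) numeric(0) else unlist(x$te2))
}
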