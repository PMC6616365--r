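#' Clip a trace to an x window
#'
#' Returns the contiguous run of samples from the first sample with
#' `x >= x_start` to the last sample with `x <= x_end`. Clipping is by
#' threshold crossing on recorded samples; boundary crossings are not
#' interpolated.
#'
#' @param trace An [new_trace()] object.
#' @param window An [x_window()].
#' @return The clipped `stt_trace`.
#' @export
clip_to_window <- function(trace, window) {
  stopifnot(inherits(trace, "stt_trace"), inherits(window, "stt_xwindow"))
  issues <- validate_trace(trace)
  if (length(issues)) stop("invalid trace: ", issues[1])
  x <- trace$samples$x_mm
  i1 <- which(x >= window$x_start)
  i2 <- which(x <= window$x_end)
  if (!length(i1) || !length(i2) || i1[1] > i2[length(i2)])
    stop(sprintf("no samples inside window [%g, %g]",
                 window$x_start, window$x_end))
  idx <- i1[1]:i2[length(i2)]
  if (length(idx) < 2)
    stop(sprintf("fewer than 2 samples inside window [%g, %g]",
                 window$x_start, window$x_end))
  out <- trace
  out$samples <- trace$samples[idx, , drop = FALSE]
  rownames(out$samples) <- NULL
  out
}

#' Tracing accuracy: summed distance to the task curve
#'
#' Sum over all recorded samples of the distance from the pen position to the
#' task curve, in mm. The larger the deviation of the traced line from the
#' target wave, the larger this value. Sums are over recorded samples with no
#' resampling; see [point_to_curve_distance()] for the two distance modes.
#'
#' @param trace A trace already clipped to an in-span window.
#' @param figure An `stt_task_figure`.
#' @param mode `"nearest"` (default) or `"vertical"`.
#' @return Summed distance, mm.
#' @export
tracing_accuracy <- function(trace, figure, mode = c("nearest", "vertical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "stt_trace"))
  s <- trace$samples
  sum(point_to_curve_distance(figure, s$x_mm, s$y_mm, mode = mode))
}

#' Summed pen-pressure change
#'
#' Total of the absolute pressure differences between consecutive samples,
#' `sum(|p[i+1] - p[i]|)`, in device units. Zero iff the pressure is constant;
#' it grows when the tracing is not smooth (tremulous pressure, pen lifts).
#'
#' @param trace An `stt_trace` with at least 2 samples.
#' @return Summed absolute pressure change, device units.
#' @export
pressure_change_sum <- function(trace) {
  p <- .trace_pressure(trace)
  sum(abs(diff(p)))
}

#' Maximum pen-pressure change
#'
#' Largest absolute pressure difference between consecutive samples, in
#' device units. A pen detaching from the surface produces a sudden drop to
#' zero that dominates this value.
#'
#' @inheritParams pressure_change_sum
#' @return Maximum absolute pressure change, device units.
#' @export
pressure_change_max <- function(trace) {
  p <- .trace_pressure(trace)
  max(abs(diff(p)))
}

.trace_pressure <- function(trace) {
  stopifnot(inherits(trace, "stt_trace"))
  p <- trace$samples$pressure
  if (length(p) < 2) stop("need at least 2 samples")
  p
}

#' Tracing duration
#'
#' Time from the first to the last recorded sample of the (clipped) trace,
#' in seconds.
#'
#' @inheritParams pressure_change_sum
#' @return Duration in seconds.
#' @export
tracing_duration <- function(trace) {
  stopifnot(inherits(trace, "stt_trace"))
  t <- trace$samples$t_ms
  if (length(t) < 2) stop("need at least 2 samples")
  (t[length(t)] - t[1]) / 1000
}

#' Extract the four STT variables from a trace
#'
#' Clips the trace to the figure's [analysis_window()] (first and last half
#' cycles excluded), then computes tracing accuracy, summed pressure change,
#' maximum pressure change, and duration on the clipped trace. The start and
#' end of the test are the first and last recorded samples of the clipped
#' trace.
#'
#' @param trace A valid `stt_trace` covering the analysis window.
#' @param figure An `stt_task_figure`.
#' @param mode Distance mode, see [tracing_accuracy()].
#' @param window Optional [x_window()] to use instead of the full analysis
#'   window (used for one-cycle segments).
#' @return An object of class `stt_features`: a list with elements
#'   `tracing_accuracy`, `pressure_change_sum`, `pressure_change_max`,
#'   `duration`, `n_samples`, `window`.
#' @export
extract_features <- function(trace, figure, mode = c("nearest", "vertical"),
                             window = NULL) {
  mode <- match.arg(mode)
  if (is.null(window)) window <- analysis_window(figure)
  clipped <- clip_to_window(trace, window)
  fv <- list(tracing_accuracy = tracing_accuracy(clipped, figure, mode),
             pressure_change_sum = pressure_change_sum(clipped),
             pressure_change_max = pressure_change_max(clipped),
             duration = tracing_duration(clipped),
             n_samples = nrow(clipped$samples),
             window = window)
  class(fv) <- "stt_features"
  fv
}

#' @export
print.stt_features <- function(x, ...) {
  cat(sprintf(paste0(
    "<stt_features> accuracy %.2f mm, pressure-change sum %.1f,",
    " pressure-change max %.1f, duration %.2f s (%d samples in [%g, %g])\n"),
    x$tracing_accuracy, x$pressure_change_sum, x$pressure_change_max,
    x$duration, x$n_samples, x$window$x_start, x$window$x_end))
  invisible(x)
}

#' Per-cycle feature vectors
#'
#' Computes one feature vector per one-cycle window of the figure (see
#' [cycle_windows()]), in tracing order, for reliability analysis of
#' single-cycle segments.
#'
#' @inheritParams extract_features
#' @return List of `stt_features`, one per cycle window.
#' @export
cycle_features <- function(trace, figure, mode = c("nearest", "vertical")) {
  mode <- match.arg(mode)
  wins <- cycle_windows(figure)
  lapply(seq_along(wins), function(i) {
    tryCatch(
      extract_features(trace, figure, mode = mode, window = wins[[i]]),
      error = function(e)
        stop(sprintf("cycle %d: %s", i, conditionMessage(e)), call. = FALSE))
  })
}

#' Coerce features to a numeric matrix
#'
#' @param features A list of `stt_features`, a single `stt_features`, or a
#'   `data.frame` containing the four feature columns.
#' @return Numeric matrix with columns `tracing_accuracy`,
#'   `pressure_change_sum`, `pressure_change_max`, `duration` — the fixed
#'   input order of the scoring network.
#' @export
feature_matrix <- function(features) {
  if (inherits(features, "stt_features")) features <- list(features)
  if (is.data.frame(features)) {
    .check_feature_matrix_cols(features)
    m <- as.matrix(features[, .feature_cols, drop = FALSE])
  } else if (is.list(features)) {
    m <- t(vapply(features, function(fv) {
      stopifnot(inherits(fv, "stt_features"))
      c(fv$tracing_accuracy, fv$pressure_change_sum,
        fv$pressure_change_max, fv$duration)
    }, numeric(4)))
    colnames(m) <- .feature_cols
  } else {
    stop("cannot coerce object of class ", class(features)[1],
         " to a feature matrix")
  }
  storage.mode(m) <- "double"
  m
}

.check_feature_matrix_cols <- function(df) {
  miss <- setdiff(.feature_cols, names(df))
  if (length(miss))
    stop("missing feature column(s): ", paste(miss, collapse = ", "))
}

#' Feature table for a labeled cohort of traces
#'
#' @param traces List of `stt_trace`.
#' @param figure An `stt_task_figure`.
#' @param mode Distance mode.
#' @return `data.frame` in the feature-table schema (see
#'   [write_feature_table()]); groups are taken from each trace.
#' @export
cohort_feature_table <- function(traces, figure,
                                 mode = c("nearest", "vertical")) {
  mode <- match.arg(mode)
  rows <- lapply(traces, function(tr) {
    fv <- extract_features(tr, figure, mode = mode)
    data.frame(subject_id = tr$subject_id, group = tr$group,
               tracing_accuracy = fv$tracing_accuracy,
               pressure_change_sum = fv$pressure_change_sum,
               pressure_change_max = fv$pressure_change_max,
               duration = fv$duration,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
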