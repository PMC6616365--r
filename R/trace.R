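#' Construct a pen trace
#'
#' A trace is an ordered series of time-stamped pen samples with position and
#' pressure, plus subject metadata. Time is in milliseconds since trace start,
#' position in mm, pressure in raw device units (0 means the pen is not
#' touching the surface; pen lifts are encoded as pressure-0 samples, never as
#' missing rows).
#'
#' @param samples `data.frame` with numeric columns `t_ms`, `x_mm`, `y_mm`,
#'   `pressure`; at least 2 rows; `t_ms` strictly increasing; `pressure >= 0`.
#' @param subject_id Subject identifier string.
#' @param group One of `"patient"`, `"control"`, `"unknown"`.
#' @param hand `"dominant"` or `"nondominant"`.
#' @param device_pressure_max Full-scale pressure of the device, device units.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#' @return An object of class `stt_trace`.
#' @export
new_trace <- function(samples, subject_id = "unknown",
                      group = c("unknown", "patient", "control"),
                      hand = c("dominant", "nondominant"),
                      device_pressure_max = 1023, validate = TRUE) {
  group <- match.arg(group)
  hand <- match.arg(hand)
  stopifnot(is.data.frame(samples))
  tr <- structure(
    list(samples = samples,
         subject_id = as.character(subject_id),
         group = group,
         hand = hand,
         device_pressure_max = as.numeric(device_pressure_max)),
    class = "stt_trace")
  if (validate) {
    issues <- validate_trace(tr)
    if (length(issues))
      stop("invalid trace: ", paste(issues, collapse = "; "))
  }
  tr
}

#' @export
print.stt_trace <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("<stt_trace> subject '%s' (%s, %s hand): %d samples",
              x$subject_id, x$group, x$hand, n))
  if (n >= 2)
    cat(sprintf(", %.2f s, x in [%.1f, %.1f] mm",
                (x$samples$t_ms[n] - x$samples$t_ms[1]) / 1000,
                min(x$samples$x_mm), max(x$samples$x_mm)))
  cat("\n")
  invisible(x)
}

#' Validate a pen trace
#'
#' Checks every trace invariant and reports violations instead of stopping.
#' Each issue names the violated invariant and, where applicable, the first
#' offending sample index.
#'
#' @param trace An `stt_trace` (or a bare list with the same fields).
#' @return Character vector of issues; empty when the trace is valid.
#' @export
validate_trace <- function(trace) {
  issues <- character(0)
  s <- trace$samples
  need <- c("t_ms", "x_mm", "y_mm", "pressure")
  miss <- setdiff(need, names(s))
  if (length(miss))
    return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  for (col in need) {
    if (!is.numeric(s[[col]])) {
      issues <- c(issues, sprintf("column '%s' is not numeric", col))
    } else if (any(!is.finite(s[[col]]))) {
      issues <- c(issues, sprintf("non-finite value in '%s' at index %d",
                                  col, which(!is.finite(s[[col]]))[1]))
    }
  }
  if (length(issues)) return(issues)
  if (nrow(s) < 2)
    issues <- c(issues, sprintf("too few samples (%d; need >= 2)", nrow(s)))
  if (nrow(s) >= 2) {
    dt <- diff(s$t_ms)
    if (any(dt <= 0))
      issues <- c(issues, sprintf("t_ms not strictly increasing at index %d",
                                  which(dt <= 0)[1] + 1L))
  }
  if (any(s$t_ms < 0))
    issues <- c(issues, sprintf("negative t_ms at index %d",
                                which(s$t_ms < 0)[1]))
  if (any(s$pressure < 0))
    issues <- c(issues, sprintf("negative pressure at index %d",
                                which(s$pressure < 0)[1]))
  issues
}

# Map cohort labels onto the two diagnostic classes. "control" and "healthy"
# are synonyms; trace metadata uses "control", classifier output uses
# "healthy".
normalize_group <- function(g) {
  g <- as.character(g)
  out <- ifelse(g %in% c("control", "healthy"), "healthy",
                ifelse(g == "patient", "patient", NA_character_))
  if (any(is.na(out)))
    stop("group labels must be 'patient', 'control' or 'healthy'; got: ",
         paste(unique(g[is.na(out)]), collapse = ", "))
  out
}
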