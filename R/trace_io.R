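#' Trace CSV format
#'
#' Traces are stored as plain UTF-8 CSV with LF line endings: leading
#' `# key=value` metadata lines (sorted by key), a fixed header
#' `t_ms,x_mm,y_mm,pressure`, then one row per sample. Numbers are written
#' with round-trip-faithful precision, so writing the same trace twice is
#' byte-identical and a write/read cycle reproduces the trace exactly.
#'
#' @param trace An [new_trace()] object.
#' @param path File path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a validated `stt_trace`.
#' @name trace_csv
NULL

.fmt_num <- function(v) {
  out <- sprintf("%.17g", v)
  # trim to the shortest representation that still round-trips
  short <- sprintf("%.15g", v)
  ok <- as.numeric(short) == v
  out[ok] <- short[ok]
  out
}

.trace_header <- "t_ms,x_mm,y_mm,pressure"

#' @rdname trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "stt_trace"))
  issues <- validate_trace(trace)
  if (length(issues)) stop("refusing to write invalid trace: ", issues[1])
  meta <- c(device_pressure_max = .fmt_num(trace$device_pressure_max),
            group = trace$group,
            hand = trace$hand,
            subject_id = trace$subject_id)
  meta <- meta[order(names(meta))]
  s <- trace$samples
  lines <- c(sprintf("# %s=%s", names(meta), unname(meta)),
             .trace_header,
             paste(.fmt_num(s$t_ms), .fmt_num(s$x_mm), .fmt_num(s$y_mm),
                   .fmt_num(s$pressure), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  body <- lines[!is_meta]
  body_lineno <- which(!is_meta)

  meta <- list()
  for (ml in meta_lines) {
    m <- regmatches(ml, regexec("^#\\s*([^=]+)=(.*)$", ml))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- m[3]
  }

  keep <- nzchar(trimws(body))
  body_lineno <- body_lineno[keep]
  body <- body[keep]
  if (!length(body)) stop("format error: no header row in ", path)
  if (trimws(body[1]) != .trace_header)
    stop("format error: expected header '", .trace_header, "', got '",
         body[1], "'")
  data_lines <- body[-1]
  data_linenos <- body_lineno[-1]
  if (length(data_lines) < 2)
    stop("validation error: trace needs at least 2 samples, got ",
         length(data_lines))

  fields <- strsplit(data_lines, ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L)) {
    bad <- which(nf != 4L)[1]
    stop(sprintf("format error: line %d has %d column(s), expected 4",
                 data_linenos[bad], nf[bad]))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = 4, byrow = TRUE)
  if (any(is.na(mat))) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    stop(sprintf("parse error: non-numeric cell on line %d",
                 data_linenos[bad]))
  }
  samples <- data.frame(t_ms = mat[, 1], x_mm = mat[, 2],
                        y_mm = mat[, 3], pressure = mat[, 4])

  tr <- new_trace(
    samples,
    subject_id = if (!is.null(meta$subject_id)) meta$subject_id else "unknown",
    group = if (!is.null(meta$group)) meta$group else "unknown",
    hand = if (!is.null(meta$hand)) meta$hand else "dominant",
    device_pressure_max = if (!is.null(meta$device_pressure_max))
      as.numeric(meta$device_pressure_max) else 1023,
    validate = FALSE)
  issues <- validate_trace(tr)
  if (length(issues))
    stop("validation error in ", path, ": ", paste(issues, collapse = "; "))
  tr
}

#' Read or write an STT feature table
#'
#' Feature tables have columns `subject_id`, `group`, `tracing_accuracy`,
#' `pressure_change_sum`, `pressure_change_max`, `duration`. This is also the
#' schema any externally supplied training/validation feature set must be
#' coerced to; an optional `split` column (`"training"` / `"validation"`) is
#' preserved when present.
#'
#' @param features A `data.frame` with the columns above.
#' @param path File path.
#' @return `read_feature_table()` returns the checked `data.frame`.
#' @export
write_feature_table <- function(features, path) {
  .check_feature_table(features)
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .check_feature_table(df)
  df
}

.feature_cols <- c("tracing_accuracy", "pressure_change_sum",
                   "pressure_change_max", "duration")

.check_feature_table <- function(df) {
  need <- c("subject_id", "group", .feature_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("feature table missing column(s): ", paste(miss, collapse = ", "))
  for (col in .feature_cols)
    if (!is.numeric(df[[col]]))
      stop("feature column '", col, "' is not numeric")
  invisible(df)
}
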