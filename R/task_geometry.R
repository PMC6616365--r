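#' Sine-wave task figure
#'
#' The tracing target is a sine wave of `n_cycles` full periods, drawn from
#' left to right. The coordinate system has x increasing along the tracing
#' direction and y increasing upward, both in millimetres, with the origin at
#' the start of the wave on its centreline. The clinical task uses a 4-cycle
#' wave with amplitude 35 mm and wavelength 62 mm, which are the defaults.
#'
#' @param amplitude Peak deviation from the centreline, mm. Must be > 0.
#' @param wavelength Length of one full cycle along x, mm. Must be > 0.
#' @param n_cycles Number of full cycles, integer >= 1.
#' @param x_origin x coordinate of the wave start, mm.
#' @return An object of class `stt_task_figure`.
#' @examples
#' fig <- task_figure()
#' task_curve_y(fig, 62 / 4) # one quarter wavelength in: the first peak, 35 mm
#' @export
task_figure <- function(amplitude = 35, wavelength = 62, n_cycles = 4L,
                        x_origin = 0) {
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L, is.finite(amplitude),
            is.numeric(wavelength), length(wavelength) == 1L, is.finite(wavelength),
            is.numeric(n_cycles), length(n_cycles) == 1L, is.finite(n_cycles),
            is.numeric(x_origin), length(x_origin) == 1L, is.finite(x_origin))
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  if (wavelength <= 0) stop("'wavelength' must be > 0")
  if (n_cycles < 1 || n_cycles != round(n_cycles))
    stop("'n_cycles' must be a positive integer")
  structure(
    list(amplitude = as.numeric(amplitude),
         wavelength = as.numeric(wavelength),
         n_cycles = as.integer(n_cycles),
         x_origin = as.numeric(x_origin)),
    class = "stt_task_figure"
  )
}

#' @export
print.stt_task_figure <- function(x, ...) {
  cat(sprintf(
    "<stt_task_figure> amplitude %g mm, wavelength %g mm, %d cycle(s), origin x = %g mm\n",
    x$amplitude, x$wavelength, x$n_cycles, x$x_origin))
  invisible(x)
}

#' x span covered by a task figure
#'
#' @param figure An `stt_task_figure`.
#' @return Numeric length-2 vector `c(x_start, x_end)` in mm; the width is
#'   `n_cycles * wavelength`.
#' @export
figure_span <- function(figure) {
  stopifnot(inherits(figure, "stt_task_figure"))
  c(figure$x_origin, figure$x_origin + figure$n_cycles * figure$wavelength)
}

.assert_in_span <- function(figure, x, tol = 1e-9) {
  sp <- figure_span(figure)
  if (any(x < sp[1] - tol | x > sp[2] + tol))
    stop(sprintf("x outside the figure span [%g, %g] mm", sp[1], sp[2]))
  invisible(TRUE)
}

#' Evaluate the task curve
#'
#' Height of the target sine wave at horizontal position `x`:
#' `A * sin(2 * pi * (x - x_origin) / wavelength)`. The curve is 0 at the
#' origin and at every half-wavelength.
#'
#' @param figure An `stt_task_figure`.
#' @param x Numeric vector of positions, mm; must lie within [figure_span].
#' @return y of the curve at `x`, mm.
#' @export
task_curve_y <- function(figure, x) {
  stopifnot(inherits(figure, "stt_task_figure"), is.numeric(x), all(is.finite(x)))
  .assert_in_span(figure, x)
  figure$amplitude * sin(2 * pi * (x - figure$x_origin) / figure$wavelength)
}

#' An interval on the x axis
#'
#' @param x_start,x_end Interval bounds in mm, `x_start < x_end`.
#' @return An object of class `stt_xwindow`.
#' @export
x_window <- function(x_start, x_end) {
  stopifnot(is.numeric(x_start), length(x_start) == 1L, is.finite(x_start),
            is.numeric(x_end), length(x_end) == 1L, is.finite(x_end))
  if (!(x_start < x_end)) stop("'x_start' must be < 'x_end'")
  structure(list(x_start = as.numeric(x_start), x_end = as.numeric(x_end)),
            class = "stt_xwindow")
}

#' @export
print.stt_xwindow <- function(x, ...) {
  cat(sprintf("<stt_xwindow> [%g, %g] mm\n", x$x_start, x$x_end))
  invisible(x)
}

#' Analysis window of a task figure
#'
#' The evaluated stretch excludes the first and last half cycles of the wave,
#' so for an `n`-cycle figure the window is
#' `[x_origin + lambda/2, x_origin + (n - 1/2) * lambda]` — an interval of
#' `n - 1` full cycles (3 cycles for the default 4-cycle figure).
#'
#' @param figure An `stt_task_figure` with `n_cycles >= 2`.
#' @return An [x_window()].
#' @export
analysis_window <- function(figure) {
  stopifnot(inherits(figure, "stt_task_figure"))
  if (figure$n_cycles < 2)
    stop("analysis window needs n_cycles >= 2 (half-cycle exclusion would empty it)")
  lam <- figure$wavelength
  x_window(figure$x_origin + lam / 2,
           figure$x_origin + (figure$n_cycles - 0.5) * lam)
}

#' One-cycle windows within the analysis window
#'
#' Partitions the analysis window into `n_cycles - 1` contiguous windows of
#' one wavelength each, used to score single-cycle segments for reliability
#' analysis.
#'
#' @inheritParams analysis_window
#' @return List of [x_window()] objects, in tracing order.
#' @export
cycle_windows <- function(figure) {
  aw <- analysis_window(figure)
  lam <- figure$wavelength
  n <- figure$n_cycles - 1L
  lapply(seq_len(n), function(i) {
    x_window(aw$x_start + (i - 1) * lam, aw$x_start + i * lam)
  })
}

# Nearest-point distance to the curve: coarse argmin on a dense grid
# (2048 samples per wavelength), then a clamped Newton refinement of the
# squared distance within one grid cell, to 1e-6 mm. The grid scan per point
# is restricted to |u - x| <= d_vert, which is exact: the distance to any
# curve point (u, f(u)) is at least |u - x|, and d_vert is an upper bound on
# the minimum. The vertical candidate u = x is always included so
# nearest <= vertical holds exactly.
.curve_nearest_distance <- function(figure, x, y,
                                    grid_per_wavelength = 2048L, tol = 1e-6) {
  A <- figure$amplitude
  om <- 2 * pi / figure$wavelength
  x0 <- figure$x_origin
  sp <- figure_span(figure)
  f <- function(u) A * sin(om * (u - x0))

  n_grid <- grid_per_wavelength * figure$n_cycles
  us <- seq(sp[1], sp[2], length.out = n_grid + 1L)
  vs <- f(us)
  h_grid <- us[2] - us[1]

  n <- length(x)
  best_u <- numeric(n)
  dv <- abs(y - f(x))
  lo <- pmax(findInterval(x - dv - h_grid, us), 1L)
  hi <- pmin(findInterval(x + dv + h_grid, us) + 1L, length(us))
  for (i in seq_len(n)) {
    ui <- lo[i]:hi[i]
    d2 <- (us[ui] - x[i])^2 + (vs[ui] - y[i])^2
    best_u[i] <- us[ui[which.min(d2)]]
  }

  h <- h_grid
  u <- best_u
  for (iter in 1:20) {
    fu <- f(u)
    fp <- A * om * cos(om * (u - x0))
    fpp <- -A * om^2 * sin(om * (u - x0))
    g <- 2 * (u - x) + 2 * (fu - y) * fp
    hess <- 2 + 2 * (fp^2 + (fu - y) * fpp)
    step <- g / pmax(hess, 1e-8)
    step <- pmin(pmax(step, -h), h)
    u <- u - step
    u <- pmin(pmax(u, best_u - h), best_u + h)
    u <- pmin(pmax(u, sp[1]), sp[2])
    if (max(abs(step)) < tol) break
  }

  d_ref <- sqrt((u - x)^2 + (f(u) - y)^2)
  d_grid <- sqrt((best_u - x)^2 + (f(best_u) - y)^2)
  d_vert <- abs(y - f(x))
  pmin(d_ref, d_grid, d_vert)
}

#' Distance from a point to the task curve
#'
#' Two readings of "distance between the traced figure and the task figure"
#' are supported. `"vertical"` is the absolute y difference at the sample's x.
#' `"nearest"` (the default) is the minimum Euclidean distance from the point
#' to the curve, found by dense sampling plus local refinement; it is always
#' less than or equal to the vertical distance and remains well defined where
#' a trace doubles back in x.
#'
#' @param figure An `stt_task_figure`.
#' @param x,y Point coordinates in mm; vectors of equal length. `x` must lie
#'   within the figure span.
#' @param mode `"nearest"` or `"vertical"`.
#' @return Distance(s) in mm, same length as `x`.
#' @export
point_to_curve_distance <- function(figure, x, y,
                                    mode = c("nearest", "vertical")) {
  mode <- match.arg(mode)
  stopifnot(inherits(figure, "stt_task_figure"),
            is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  .assert_in_span(figure, x)
  if (mode == "vertical") {
    abs(y - task_curve_y(figure, x))
  } else {
    .curve_nearest_distance(figure, x, y)
  }
}

#' Read or write a task-figure JSON configuration
#'
#' The JSON schema uses keys `amplitude_mm`, `wavelength_mm`, `n_cycles`,
#' `x_origin_mm`.
#'
#' @param path File path.
#' @return `read_figure_config()` returns an `stt_task_figure`;
#'   `write_figure_config()` returns `path` invisibly.
#' @export
read_figure_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("amplitude_mm", "wavelength_mm", "n_cycles", "x_origin_mm")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("figure config missing key(s): ", paste(miss, collapse = ", "))
  task_figure(cfg$amplitude_mm, cfg$wavelength_mm, cfg$n_cycles, cfg$x_origin_mm)
}

#' @rdname read_figure_config
#' @param figure An `stt_task_figure` to serialize.
#' @export
write_figure_config <- function(figure, path) {
  stopifnot(inherits(figure, "stt_task_figure"))
  jsonlite::write_json(
    list(amplitude_mm = figure$amplitude, wavelength_mm = figure$wavelength,
         n_cycles = figure$n_cycles, x_origin_mm = figure$x_origin),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
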