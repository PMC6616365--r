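#' Motor profile of a simulated tracer
#'
#' Generative description of how a (simulated) subject traces the wave: the
#' pen advances along x at constant `speed`, sampled at `sample_rate`; the
#' vertical position is the task curve plus Gaussian tracking noise
#' (`deviation_sd`) plus a sinusoidal tremor; pressure is Gaussian around
#' `pressure_mean`, clipped at 0, with Poisson-distributed pen lifts that
#' drop the pressure to 0 for `lift_duration` ms.
#'
#' @param deviation_sd Tracking-noise sd, mm.
#' @param tremor_amplitude Tremor amplitude, mm.
#' @param tremor_freq Tremor frequency, Hz.
#' @param lift_rate Expected number of pen lifts per trace.
#' @param lift_duration Duration of a lift, ms.
#' @param speed Horizontal pen speed, mm/s (> 0).
#' @param pressure_mean,pressure_sd Pressure distribution, device units.
#' @param sample_rate Sampling rate, Hz (> 0).
#' @return An object of class `stt_motor_profile`.
#' @export
motor_profile <- function(deviation_sd, tremor_amplitude, tremor_freq,
                          lift_rate, lift_duration, speed,
                          pressure_mean, pressure_sd, sample_rate = 100) {
  vals <- c(deviation_sd = deviation_sd, tremor_amplitude = tremor_amplitude,
            tremor_freq = tremor_freq, lift_rate = lift_rate,
            lift_duration = lift_duration, speed = speed,
            pressure_mean = pressure_mean, pressure_sd = pressure_sd,
            sample_rate = sample_rate)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all motor-profile fields must be finite and non-negative")
  if (speed <= 0) stop("'speed' must be > 0")
  if (sample_rate <= 0) stop("'sample_rate' must be > 0")
  structure(as.list(vals), class = "stt_motor_profile")
}

#' Default control and patient motor profiles
#'
#' Documented defaults emulating the contrast between healthy tracers and
#' tracers with impaired hand dexterity: the patient profile has at least
#' twice the control's tracking noise, tremor amplitude, lift rate and time
#' per mm (i.e. half the speed or less), and a spikier pressure signal.
#' Pressure is on a 0-1023 device scale sampled at 100 Hz.
#'
#' @return `list(control = , patient = )` of [motor_profile()] objects.
#' @export
default_profiles <- function() {
  list(
    control = motor_profile(
      deviation_sd = 1.0, tremor_amplitude = 0.3, tremor_freq = 5,
      lift_rate = 0, lift_duration = 100, speed = 25,
      pressure_mean = 520, pressure_sd = 8, sample_rate = 100),
    patient = motor_profile(
      deviation_sd = 3.0, tremor_amplitude = 1.2, tremor_freq = 5.5,
      lift_rate = 2, lift_duration = 150, speed = 10,
      pressure_mean = 480, pressure_sd = 30, sample_rate = 100))
}

#' Simulate one pen trace
#'
#' Deterministic given `seed`. The trace covers the full figure span, so it
#' always contains the analysis window.
#'
#' @param figure An `stt_task_figure`.
#' @param profile An [motor_profile()].
#' @param seed Integer RNG seed; `NULL` uses the current RNG state (for
#'   callers that manage their own streams).
#' @param subject_id,group Metadata stored on the trace.
#' @return An `stt_trace`.
#' @export
simulate_trace <- function(figure, profile, seed = NULL,
                           subject_id = "sim", group = "unknown") {
  stopifnot(inherits(figure, "stt_task_figure"),
            inherits(profile, "stt_motor_profile"))
  if (!is.null(seed)) set.seed(seed)
  sp <- figure_span(figure)
  span <- sp[2] - sp[1]
  dt <- 1000 / profile$sample_rate                    # ms per sample
  n <- floor(span / profile$speed * profile$sample_rate) + 1L
  if (n < 2) stop("profile yields fewer than 2 samples over the figure")
  t_ms <- (seq_len(n) - 1) * dt
  x <- sp[1] + profile$speed * t_ms / 1000
  x <- pmin(x, sp[2])

  phase <- stats::runif(1, 0, 2 * pi)
  y <- task_curve_y(figure, x) +
    stats::rnorm(n, 0, profile$deviation_sd) +
    profile$tremor_amplitude *
      sin(2 * pi * profile$tremor_freq * t_ms / 1000 + phase)

  pressure <- pmax(0, stats::rnorm(n, profile$pressure_mean,
                                   profile$pressure_sd))
  n_lifts <- stats::rpois(1, profile$lift_rate)
  if (n_lifts > 0) {
    starts <- stats::runif(n_lifts, 0,
                           max(0, t_ms[n] - profile$lift_duration))
    for (s0 in starts)
      pressure[t_ms >= s0 & t_ms <= s0 + profile$lift_duration] <- 0
  }

  new_trace(data.frame(t_ms = t_ms, x_mm = x, y_mm = y, pressure = pressure),
            subject_id = subject_id, group = group)
}

#' Specification of a simulated two-group cohort
#'
#' @param n_patients,n_controls Subject counts (>= 0, at least one subject
#'   overall).
#' @param patient_profile,control_profile [motor_profile()]s; defaults from
#'   [default_profiles()].
#' @param seed Integer root seed (required).
#' @param subject_sd Log-sd of the lognormal subject-level multipliers
#'   applied to deviation_sd, tremor amplitude, lift rate, pressure sd and
#'   1/speed, so that subjects of a group differ from one another; 0 makes
#'   all subjects of a group statistically identical.
#' @return An object of class `stt_cohort_spec`.
#' @export
cohort_spec <- function(n_patients, n_controls,
                        patient_profile = default_profiles()$patient,
                        control_profile = default_profiles()$control,
                        seed, subject_sd = 0.5) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_patients >= 0, n_controls >= 0, subject_sd >= 0,
            inherits(patient_profile, "stt_motor_profile"),
            inherits(control_profile, "stt_motor_profile"))
  if (n_patients + n_controls < 1) stop("cohort must contain at least 1 subject")
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 patient_profile = patient_profile,
                 control_profile = control_profile,
                 seed = as.integer(seed),
                 subject_sd = subject_sd),
            class = "stt_cohort_spec")
}

.jitter_profile <- function(profile, subject_sd) {
  if (subject_sd == 0) return(profile)
  m <- stats::rlnorm(5, 0, subject_sd)
  motor_profile(
    deviation_sd = profile$deviation_sd * m[1],
    tremor_amplitude = profile$tremor_amplitude * m[2],
    tremor_freq = profile$tremor_freq,
    lift_rate = profile$lift_rate * m[3],
    lift_duration = profile$lift_duration,
    speed = profile$speed / m[4],
    pressure_mean = profile$pressure_mean,
    pressure_sd = profile$pressure_sd * m[5],
    sample_rate = profile$sample_rate)
}

#' Simulate a labeled cohort of traces
#'
#' Two child seeds are derived deterministically from the root seed for every
#' subject (one for the subject-level profile jitter, one for the trace), so
#' cohorts are reproducible and per-subject streams are disjoint regardless
#' of generation order.
#'
#' @param figure An `stt_task_figure`.
#' @param spec An [cohort_spec()].
#' @return List with `traces` (list of `stt_trace`), `labels` (character),
#'   and `manifest` (`data.frame` of subject_id, group, seed).
#' @export
simulate_cohort <- function(figure, spec) {
  stopifnot(inherits(figure, "stt_task_figure"),
            inherits(spec, "stt_cohort_spec"))
  n_total <- spec$n_patients + spec$n_controls
  groups <- c(rep("patient", spec$n_patients),
              rep("control", spec$n_controls))
  ids <- sprintf("%s%02d",
                 ifelse(groups == "patient", "P", "C"),
                 c(seq_len(spec$n_patients), seq_len(spec$n_controls)))

  set.seed(spec$seed)
  child <- sample.int(.Machine$integer.max - 1L, 2L * n_total)

  traces <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    prof <- if (groups[i] == "patient") spec$patient_profile
            else spec$control_profile
    set.seed(child[2L * i - 1L])
    prof_i <- .jitter_profile(prof, spec$subject_sd)
    traces[[i]] <- simulate_trace(figure, prof_i, seed = child[2L * i],
                                  subject_id = ids[i], group = groups[i])
  }
  list(traces = traces,
       labels = groups,
       manifest = data.frame(subject_id = ids, group = groups,
                             seed = child[seq(2L, 2L * n_total, by = 2L)],
                             stringsAsFactors = FALSE))
}

#' Intra-observer reliability of per-cycle scores
#'
#' Mirrors the reliability protocol of the clinical study on any pair of
#' labeled trace cohorts: one-cycle segments are extracted from every trace
#' ([cycle_features()]), a network is trained on the per-cycle vectors of the
#' training cohort (each labeled with its subject's group), the per-cycle
#' vectors of the validation cohort are scored, and the intra-class
#' correlation of the resulting n-subjects x n-cycles score matrix is
#' computed.
#'
#' @param train_traces,val_traces Lists of `stt_trace` with group metadata.
#' @param figure An `stt_task_figure`.
#' @param config A [train_config()].
#' @param mode Distance mode for feature extraction.
#' @param icc_model Passed to [icc()].
#' @return List with `icc` (an `stt_icc`), `scores` (matrix, one row per
#'   validation subject, one column per cycle), `groups` (validation labels)
#'   and `params` (the trained `stt_mlp`).
#' @export
cycle_reliability <- function(train_traces, val_traces, figure, config,
                              mode = c("nearest", "vertical"),
                              icc_model = c("consistency", "agreement")) {
  mode <- match.arg(mode)
  icc_model <- match.arg(icc_model)

  per_cycle <- function(traces) {
    feats <- list(); labs <- character(0); subj <- character(0)
    for (tr in traces) {
      cf <- tryCatch(cycle_features(tr, figure, mode = mode),
                     error = function(e)
                       stop(sprintf("subject '%s': %s", tr$subject_id,
                                    conditionMessage(e)), call. = FALSE))
      feats <- c(feats, cf)
      labs <- c(labs, rep(tr$group, length(cf)))
      subj <- c(subj, rep(tr$subject_id, length(cf)))
    }
    list(features = feats, labels = labs, subjects = subj)
  }

  tr_set <- per_cycle(train_traces)
  va_set <- per_cycle(val_traces)
  params <- train_mlp(tr_set$features, tr_set$labels, config)
  scores <- score_feature_table(params, va_set$features)

  k <- length(cycle_windows(figure))
  subj_ids <- unique(va_set$subjects)
  mat <- matrix(NA_real_, length(subj_ids), k,
                dimnames = list(subj_ids, paste0("cycle", seq_len(k))))
  for (i in seq_along(scores))
    mat[va_set$subjects[i],
        ((i - 1L) %% k) + 1L] <- scores[i]
  groups <- vapply(val_traces, function(tr) tr$group, character(1))

  list(icc = icc(mat, model = icc_model), scores = mat,
       groups = groups, params = params)
}
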