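#' Empirical ROC curve with distance-to-corner cutoff
#'
#' Builds the empirical ROC over candidate thresholds placed at the midpoints
#' between consecutive distinct sorted scores, plus -Inf and +Inf sentinels.
#' With `direction = "lower_is_positive"` a subject is called positive
#' (patient) when its score is below the threshold; with
#' `"higher_is_positive"` when above. Sensitivity is the fraction of
#' positives called positive, specificity the fraction of negatives called
#' negative. The optimal cutoff minimizes
#' `(1 - sensitivity)^2 + (1 - specificity)^2` (see [optimal_cutoff()]), and
#' a 95% CI for the AUC is attached (see [auc_ci()]).
#'
#' @param scores Finite numeric scores.
#' @param labels Group labels; `"patient"` is the positive class,
#'   `"control"`/`"healthy"` the negative class. Both must be present.
#' @param direction `"lower_is_positive"` (default; fits the STT score where
#'   low scores indicate disease) or `"higher_is_positive"`.
#' @param ci_method `"delong"` (default, deterministic) or `"bootstrap"`.
#' @param seed Integer seed, required for the bootstrap CI.
#' @return An object of class `stt_roc` with fields `thresholds`, `sens`,
#'   `spec`, `auc`, `auc_ci`, `cutoff`, `cutoff_sens`, `cutoff_spec`,
#'   `direction`.
#' @export
roc_curve <- function(scores, labels,
                      direction = c("lower_is_positive", "higher_is_positive"),
                      ci_method = c("delong", "bootstrap"), seed = NULL) {
  direction <- match.arg(direction)
  ci_method <- match.arg(ci_method)
  g <- normalize_group(labels)
  stopifnot(length(scores) == length(g))
  if (any(!is.finite(scores))) stop("scores must be finite")
  pos <- scores[g == "patient"]
  neg <- scores[g == "healthy"]
  if (!length(pos) || !length(neg))
    stop("both classes must be present")

  su <- sort(unique(scores))
  mids <- if (length(su) > 1)
    (su[-length(su)] + su[-1]) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)

  if (direction == "lower_is_positive") {
    sens <- vapply(thr, function(th) mean(pos < th), numeric(1))
    spec <- vapply(thr, function(th) mean(neg >= th), numeric(1))
  } else {
    sens <- vapply(thr, function(th) mean(pos > th), numeric(1))
    spec <- vapply(thr, function(th) mean(neg <= th), numeric(1))
  }

  roc <- structure(
    list(thresholds = thr, sens = sens, spec = spec,
         auc = .trapezoid_auc(sens, spec),
         auc_ci = NULL, cutoff = NA_real_,
         cutoff_sens = NA_real_, cutoff_spec = NA_real_,
         direction = direction,
         n_pos = length(pos), n_neg = length(neg)),
    class = "stt_roc")

  cut <- optimal_cutoff(roc)
  i <- which(thr == cut)[1]
  roc$cutoff <- cut
  roc$cutoff_sens <- sens[i]
  roc$cutoff_spec <- spec[i]
  roc$auc_ci <- auc_ci(scores, g, direction, method = ci_method, seed = seed)
  roc
}

#' @export
print.stt_roc <- function(x, ...) {
  cat(sprintf(
    "<stt_roc> %d patients vs %d healthy (%s)\n  AUC %.3f (95%% CI %.3f-%.3f); cutoff %.3g (sens %.2f, spec %.2f)\n",
    x$n_pos, x$n_neg, x$direction, x$auc, x$auc_ci[1], x$auc_ci[2],
    x$cutoff, x$cutoff_sens, x$cutoff_spec))
  invisible(x)
}

.trapezoid_auc <- function(sens, spec) {
  fpr <- 1 - spec
  o <- order(fpr, sens)
  fpr <- fpr[o]; tpr <- sens[o]
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Area under the empirical ROC curve
#'
#' Trapezoidal area under the ROC of [roc_curve()]. It equals the
#' Mann-Whitney pair statistic (fraction of patient/healthy pairs ranked in
#' the indicated direction, ties counted 1/2).
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels,
                direction = c("lower_is_positive", "higher_is_positive")) {
  direction <- match.arg(direction)
  g <- normalize_group(labels)
  pos <- scores[g == "patient"]; neg <- scores[g == "healthy"]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  su <- sort(unique(scores))
  mids <- if (length(su) > 1) (su[-length(su)] + su[-1]) / 2 else numeric(0)
  thr <- c(-Inf, mids, Inf)
  if (direction == "lower_is_positive") {
    sens <- vapply(thr, function(th) mean(pos < th), numeric(1))
    spec <- vapply(thr, function(th) mean(neg >= th), numeric(1))
  } else {
    sens <- vapply(thr, function(th) mean(pos > th), numeric(1))
    spec <- vapply(thr, function(th) mean(neg <= th), numeric(1))
  }
  .trapezoid_auc(sens, spec)
}

# Mann-Whitney AUC via ranks; used by the bootstrap resampler.
.mw_auc <- function(pos, neg, direction) {
  if (direction == "lower_is_positive") { pos <- -pos; neg <- -neg }
  m <- length(pos); n <- length(neg)
  r <- rank(c(pos, neg))
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * n)
}

#' Optimal cutoff by squared distance to the ROC corner
#'
#' Returns the threshold minimizing `(1 - sens)^2 + (1 - spec)^2` over the
#' ROC's candidate thresholds. Ties are broken by higher sensitivity, then
#' higher specificity, then smaller threshold.
#'
#' @param roc An `stt_roc` from [roc_curve()].
#' @return The cutoff threshold (a score value).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "stt_roc"))
  d2 <- (1 - roc$sens)^2 + (1 - roc$spec)^2
  o <- order(d2, -roc$sens, -roc$spec, roc$thresholds)
  roc$thresholds[o[1]]
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = tp / (tp + fn)` (patients correctly called patients),
#' `specificity = tn / (tn + fp)` (healthy correctly called healthy),
#' reported rounded half-up to 2 decimal places; the unrounded values are
#' kept in the `"raw"` attribute.
#'
#' @param tp,fn,tn,fp Non-negative integer counts; each class non-empty.
#' @return Named vector `c(sensitivity = , specificity = )`.
#' @examples
#' sens_spec_from_counts(14, 1, 15, 3) # 0.93, 0.83
#' @export
sens_spec_from_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp, fn, tn, fp)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (tp + fn < 1) stop("patient class is empty")
  if (tn + fp < 1) stop("healthy class is empty")
  raw <- c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
  out <- round_half_up(raw, 2)
  attr(out, "raw") <- raw
  out
}

#' 95% confidence interval for the AUC
#'
#' `method = "delong"` uses the DeLong variance of the Mann-Whitney AUC
#' (deterministic). `method = "bootstrap"` draws 2000 stratified resamples
#' (both classes resampled with replacement) and returns the percentile
#' interval; a seed is required. Intervals are clipped to \[0, 1\] and always
#' contain the point AUC. When the DeLong variance degenerates (e.g. AUC
#' exactly 0 or 1), a Wilson-type interval on the AUC with effective n equal
#' to the smaller class is returned with a warning.
#'
#' @inheritParams roc_curve
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @return Numeric `c(low, high)`.
#' @export
auc_ci <- function(scores, labels,
                   direction = c("lower_is_positive", "higher_is_positive"),
                   method = c("delong", "bootstrap"), seed = NULL,
                   n_boot = 2000L) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  g <- normalize_group(labels)
  pos <- scores[g == "patient"]; neg <- scores[g == "healthy"]
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  point <- .mw_auc(pos, neg, direction)

  if (method == "delong") {
    X <- if (direction == "lower_is_positive") -pos else pos
    Y <- if (direction == "lower_is_positive") -neg else neg
    M <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
    m <- length(X); n <- length(Y)
    v <- if (m >= 2 && n >= 2)
      stats::var(rowMeans(M)) / m + stats::var(colMeans(M)) / n else 0
    if (!is.finite(v) || v <= 0) {
      warning("degenerate DeLong variance; returning a Wilson-type interval")
      ci <- .wilson_ci(point, min(m, n))
    } else {
      z <- stats::qnorm(0.975)
      ci <- c(point - z * sqrt(v), point + z * sqrt(v))
    }
  } else {
    if (is.null(seed)) stop("a seed is required for the bootstrap CI")
    set.seed(seed)
    m <- length(pos); n <- length(neg)
    stat <- vapply(seq_len(n_boot), function(b) {
      .mw_auc(pos[sample.int(m, m, replace = TRUE)],
              neg[sample.int(n, n, replace = TRUE)], direction)
    }, numeric(1))
    ci <- unname(stats::quantile(stat, c(0.025, 0.975), type = 7))
  }
  ci <- c(max(0, min(ci[1], point)), min(1, max(ci[2], point)))
  ci
}

.wilson_ci <- function(p, n_eff, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  den <- 1 + z^2 / n_eff
  ctr <- (p + z^2 / (2 * n_eff)) / den
  hw <- z * sqrt(p * (1 - p) / n_eff + z^2 / (4 * n_eff^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the average ranks (ties averaged), with a two-sided
#' p value from the t approximation on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Named vector `c(rho = , p = )`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("zero rank variance; correlation undefined")
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  c(rho = rho, p = p)
}

#' Intra-class correlation of repeated ratings
#'
#' Single-measure ICC from the two-way ANOVA decomposition of an
#' n-subjects x k-ratings matrix. The default, `"consistency"`, is the
#' two-way mixed, single-measure, consistency coefficient
#' `(MS_rows - MS_error) / (MS_rows + (k - 1) * MS_error)` (ICC(3,1));
#' `"agreement"` gives the two-way random absolute-agreement coefficient
#' (ICC(2,1)). 95% confidence intervals use the standard F-distribution
#' formulas.
#'
#' @param data Numeric matrix or data.frame, subjects in rows, repeated
#'   ratings in columns; no missing cells, n >= 2, k >= 2.
#' @param model `"consistency"` (default) or `"agreement"`.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `stt_icc`: list with `icc`, `ci`, `model`,
#'   and the ANOVA mean squares.
#' @export
icc <- function(data, model = c("consistency", "agreement"), conf = 0.95) {
  model <- match.arg(model)
  m <- as.matrix(data)
  if (any(!is.finite(m))) stop("missing or non-finite cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 ratings")
  if (stats::var(as.vector(m)) == 0) stop("zero total variance")

  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(seq_len(n), times = k)),
                     rater = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ subject + rater, data = long)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]

  alpha <- 1 - conf
  if (model == "consistency") {
    value <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    if (MSE == 0) {
      ci <- c(1, 1)
    } else {
      Fobs <- MSR / MSE
      df1 <- n - 1; df2 <- (n - 1) * (k - 1)
      FL <- Fobs / stats::qf(1 - alpha / 2, df1, df2)
      FU <- Fobs * stats::qf(1 - alpha / 2, df2, df1)
      ci <- c((FL - 1) / (FL + k - 1), (FU - 1) / (FU + k - 1))
    }
    label <- "two-way mixed, single measure, consistency (ICC(3,1))"
  } else {
    value <- (MSR - MSE) /
      (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    if (MSE == 0 && MSC == 0) {
      ci <- c(1, 1)
    } else {
      a <- k * value / (n * (1 - value))
      b <- 1 + k * value * (n - 1) / (n * (1 - value))
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      F1 <- stats::qf(1 - alpha / 2, n - 1, v)
      F2 <- stats::qf(1 - alpha / 2, v, n - 1)
      lo <- n * (MSR - F1 * MSE) /
        (F1 * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      hi <- n * (F2 * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * F2 * MSR)
      ci <- c(lo, hi)
    }
    label <- "two-way random, single measure, absolute agreement (ICC(2,1))"
  }
  ci <- c(min(ci[1], value), max(ci[2], value))
  structure(list(icc = value, ci = ci, model = label,
                 ms = c(subjects = MSR, ratings = MSC, error = MSE),
                 n = n, k = k),
            class = "stt_icc")
}

#' @export
print.stt_icc <- function(x, ...) {
  cat(sprintf("<stt_icc> %.3f (95%% CI %.3f-%.3f)\n  model: %s; n = %d, k = %d\n",
              x$icc, x$ci[1], x$ci[2], x$model, x$n, x$k))
  invisible(x)
}

#' Unpaired two-sample t test
#'
#' Two-sided comparison of group means. `"student"` (default) pools the
#' variance; `"welch"` uses the Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"student"` or `"welch"`.
#' @return Named vector `c(t = , p = )` with a `"df"` attribute.
#' @export
two_sample_ttest <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      stop("both groups have zero variance and equal means; t undefined")
    out <- c(t = sign(mean(a) - mean(b)) * Inf, p = 0)
    attr(out, "df") <- length(a) + length(b) - 2
    return(out)
  }
  ht <- stats::t.test(a, b, var.equal = (variant == "student"))
  out <- c(t = unname(ht$statistic), p = ht$p.value)
  attr(out, "df") <- unname(ht$parameter)
  out
}

# Round half away from zero, matching how the clinical results are printed.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
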