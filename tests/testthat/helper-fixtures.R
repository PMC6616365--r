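# Shared fixtures and independent oracles, all built in code.

default_fig <- task_figure()

# trace sampled exactly on the task curve with constant pressure
on_curve_trace <- function(figure = default_fig, n = 400, pressure = 300,
                           dt_ms = 10, group = "unknown") {
  sp <- figure_span(figure)
  x <- seq(sp[1], sp[2], length.out = n)
  new_trace(data.frame(t_ms = (seq_len(n) - 1) * dt_ms,
                       x_mm = x,
                       y_mm = task_curve_y(figure, x),
                       pressure = rep(pressure, n)),
            group = group)
}

# randomized but valid trace for IO round-trip properties
random_valid_trace <- function(seed) {
  set.seed(seed)
  n <- sample(2:80, 1)
  new_trace(data.frame(t_ms = cumsum(runif(n, 0.5, 30)),
                       x_mm = rnorm(n, 0, 50),
                       y_mm = rnorm(n, 0, 50),
                       pressure = abs(rnorm(n, 300, 150))),
            subject_id = sprintf("R%03d", seed),
            group = sample(c("patient", "control", "unknown"), 1),
            hand = sample(c("dominant", "nondominant"), 1),
            device_pressure_max = sample(c(1023, 2047, 255), 1))
}

# Mann-Whitney pair-counting AUC oracle (ties counted 1/2)
brute_pair_auc <- function(scores, labels, direction) {
  g <- ifelse(labels %in% c("control", "healthy"), "healthy", labels)
  pos <- scores[g == "patient"]
  neg <- scores[g == "healthy"]
  tot <- 0
  for (p in pos) for (q in neg) {
    cmp <- if (direction == "lower_is_positive") sign(q - p) else sign(p - q)
    tot <- tot + (cmp > 0) + 0.5 * (cmp == 0)
  }
  tot / (length(pos) * length(neg))
}

# exhaustive confusion-matrix enumeration over all candidate thresholds
brute_roc_points <- function(scores, labels, direction) {
  g <- ifelse(labels %in% c("control", "healthy"), "healthy", labels)
  pos <- scores[g == "patient"]
  neg <- scores[g == "healthy"]
  su <- sort(unique(scores))
  thr <- c(-Inf, if (length(su) > 1) (head(su, -1) + tail(su, -1)) / 2, Inf)
  t(vapply(thr, function(th) {
    if (direction == "lower_is_positive") {
      tp <- sum(pos < th); tn <- sum(neg >= th)
    } else {
      tp <- sum(pos > th); tn <- sum(neg <= th)
    }
    c(threshold = th, sens = tp / length(pos), spec = tn / length(neg))
  }, numeric(3)))
}

# cutoff oracle: enumerate thresholds, min squared distance to the (1,1)
# corner, tie-break by higher sens, then higher spec, then smaller threshold
brute_cutoff <- function(scores, labels, direction) {
  pts <- brute_roc_points(scores, labels, direction)
  d2 <- (1 - pts[, "sens"])^2 + (1 - pts[, "spec"])^2
  o <- order(d2, -pts[, "sens"], -pts[, "spec"], pts[, "threshold"])
  pts[o[1], "threshold"]
}

# from-scratch two-way ANOVA mean squares -> consistency ICC
anova_icc_oracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse)
}

# clearly separable toy feature set: 2 clusters, n per class
separable_features <- function(n = 10, seed = 99) {
  set.seed(seed)
  pat <- data.frame(subject_id = sprintf("P%02d", 1:n), group = "patient",
                    tracing_accuracy = rnorm(n, 2000, 50),
                    pressure_change_sum = rnorm(n, 40000, 500),
                    pressure_change_max = rnorm(n, 300, 10),
                    duration = rnorm(n, 20, 0.5))
  ctl <- data.frame(subject_id = sprintf("C%02d", 1:n), group = "control",
                    tracing_accuracy = rnorm(n, 400, 50),
                    pressure_change_sum = rnorm(n, 8000, 500),
                    pressure_change_max = rnorm(n, 40, 10),
                    duration = rnorm(n, 8, 0.5))
  rbind(pat, ctl)
}
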