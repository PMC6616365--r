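test_that("reference parameters hold the published estimates exactly", {
  p <- stt_reference_params()
  # weights are indexed [hidden unit, input]
  expect_equal(p$hidden_weights[2, 1], 1.922)   # I1 -> H2
  expect_equal(p$hidden_weights[3, 1], 4.643)   # I1 -> H3
  expect_equal(p$hidden_weights[1, 2], 0.720)   # I2 -> H1
  expect_equal(p$hidden_weights[2, 3], -0.469)  # I3 -> H2
  expect_equal(p$hidden_weights[3, 4], -4.015)  # I4 -> H3
  expect_equal(p$hidden_bias, c(-0.805, 0.609, 1.315))
  expect_equal(p$output_weights[1, 2], -1.235)  # H2 -> O1
  expect_equal(p$output_weights[2, 3], -1.120)  # H3 -> O2
  expect_equal(p$output_bias, c(0.497, 0.500))
  expect_null(p$input_norm)
  expect_equal(unname(p$class_of_output), c("patient", "healthy"))
})

test_that("forward pass at zero input matches an independent scalar chain", {
  p <- stt_reference_params()
  # scalar tanh oracle: (e^a - e^-a) / (e^a + e^-a)
  tanh_oracle <- function(a) (exp(a) - exp(-a)) / (exp(a) + exp(-a))
  h <- tanh_oracle(c(-0.805, 0.609, 1.315))
  expect_equal(h, c(-0.6668, 0.5434, 0.8655), tolerance = 1e-4)
  a <- p$output_bias + drop(p$output_weights %*% h)
  expected <- exp(a) / sum(exp(a))
  got <- mlp_forward(p, c(0, 0, 0, 0))
  expect_equal(unname(got), expected, tolerance = 1e-12)
})

test_that("softmax outputs are a probability pair summing to one", {
  set.seed(5)
  for (i in 1:50) {
    p <- mlp_params(matrix(rnorm(12, sd = 3), 3, 4), rnorm(3),
                    matrix(rnorm(6, sd = 3), 2, 3), rnorm(2))
    out <- mlp_forward(p, rnorm(4, sd = 5))
    expect_equal(sum(out), 1, tolerance = 1e-12)
    expect_true(all(out > 0 & out < 1))
  }
  sym <- mlp_params(matrix(0, 3, 4), rep(0, 3), matrix(0, 2, 3), c(2, 2))
  expect_equal(unname(mlp_forward(sym, rnorm(4))), c(0.5, 0.5))
})

test_that("normalization maps means to zero and refuses unset or bad norms", {
  p <- stt_reference_params()
  fv <- structure(list(tracing_accuracy = 100, pressure_change_sum = 2000,
                       pressure_change_max = 50, duration = 12,
                       n_samples = 10, window = x_window(0, 1)),
                  class = "stt_features")
  expect_error(normalize_features(fv, p), "normalization is unset")
  expect_error(stt_score(p, fv), "normalization is unset")

  p2 <- set_input_norm(p, mean = c(100, 2000, 50, 12), sd = c(10, 100, 5, 2))
  expect_equal(unname(normalize_features(fv, p2)), c(0, 0, 0, 0))
  fv2 <- fv
  fv2$tracing_accuracy <- 110; fv2$pressure_change_sum <- 2100
  fv2$pressure_change_max <- 55; fv2$duration <- 14
  expect_equal(unname(normalize_features(fv2, p2)), c(1, 1, 1, 1))

  ident <- set_input_norm(p, mean = rep(0, 4), sd = rep(1, 4))
  expect_equal(unname(normalize_features(fv, ident)),
               c(100, 2000, 50, 12))
  expect_error(set_input_norm(p, rep(0, 4), c(1, 1, 0, 1)), "sd")
})

test_that("scores are bounded in [0, 100] and monotone in the healthy unit", {
  p <- set_input_norm(stt_reference_params(), rep(0, 4), rep(1, 4))
  set.seed(8)
  for (i in 1:30) {
    fv <- structure(list(tracing_accuracy = abs(rnorm(1, 0, 10)),
                         pressure_change_sum = abs(rnorm(1, 0, 10)),
                         pressure_change_max = abs(rnorm(1, 0, 5)),
                         duration = abs(rnorm(1, 5, 3)),
                         n_samples = 5, window = x_window(0, 1)),
                    class = "stt_features")
    s <- stt_score(p, fv)
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
  # raising the healthy-unit pre-activation strictly raises the score
  base <- mlp_params(matrix(0, 3, 4), rep(0, 3), matrix(0, 2, 3), c(0, 0),
                     input_norm = list(mean = rep(0, 4), sd = rep(1, 4)))
  fv0 <- structure(list(tracing_accuracy = 0, pressure_change_sum = 0,
                        pressure_change_max = 0, duration = 0,
                        n_samples = 2, window = x_window(0, 1)),
                   class = "stt_features")
  scores <- vapply(c(-2, 0, 1, 3), function(b2) {
    pp <- base; pp$output_bias <- c(0, b2)
    stt_score(pp, fv0)
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_equal(scores[2], 50)
})

test_that("analytic gradients match central finite differences", {
  set.seed(13)
  Z <- matrix(rnorm(32), 8, 4)
  y <- sample(0:1, 8, replace = TRUE)
  Y <- cbind(y, 1 - y)
  W1 <- matrix(rnorm(12, sd = 0.5), 3, 4); b1 <- rnorm(3, sd = 0.5)
  W2 <- matrix(rnorm(6, sd = 0.5), 2, 3); b2 <- rnorm(2, sd = 0.5)
  fg <- sttkit:::.mlp_loss_grad(W1, b1, W2, b2, Z, Y)

  loss_at <- function(W1, b1, W2, b2)
    sttkit:::.mlp_loss_grad(W1, b1, W2, b2, Z, Y)$loss
  h <- 1e-5
  check <- function(analytic, get, set) {
    for (j in seq_along(analytic)) {
      up <- set(j, h); dn <- set(j, -h)
      fd <- (loss_at(up$W1, up$b1, up$W2, up$b2) -
             loss_at(dn$W1, dn$b1, dn$W2, dn$b2)) / (2 * h)
      rel <- abs(fd - analytic[j]) / max(abs(fd), abs(analytic[j]), 1e-8)
      expect_lt(rel, 1e-6)
    }
  }
  check(as.vector(fg$gW1), NULL, function(j, d) {
    W <- W1; W[j] <- W[j] + d; list(W1 = W, b1 = b1, W2 = W2, b2 = b2) })
  check(fg$gb1, NULL, function(j, d) {
    b <- b1; b[j] <- b[j] + d; list(W1 = W1, b1 = b, W2 = W2, b2 = b2) })
  check(as.vector(fg$gW2), NULL, function(j, d) {
    W <- W2; W[j] <- W[j] + d; list(W1 = W1, b1 = b1, W2 = W, b2 = b2) })
  check(fg$gb2, NULL, function(j, d) {
    b <- b2; b[j] <- b[j] + d; list(W1 = W1, b1 = b1, W2 = W2, b2 = b) })
})

test_that("training separates a separable toy set and is seed-deterministic", {
  ft <- separable_features(n = 10)
  cfg <- train_config(seed = 123)
  p1 <- train_mlp(ft, ft$group, cfg)
  p2 <- train_mlp(ft, ft$group, cfg)
  expect_identical(p1$hidden_weights, p2$hidden_weights)
  expect_identical(p1$output_weights, p2$output_weights)

  scores <- score_feature_table(p1, ft)
  pred <- ifelse(scores < 50, "patient", "healthy")
  truth <- ifelse(ft$group == "patient", "patient", "healthy")
  expect_equal(mean(pred == truth), 1)

  log <- attr(p1, "training")
  expect_lt(log$final_loss, log$initial_loss)

  expect_error(train_mlp(ft[ft$group == "patient", ],
                         rep("patient", 10), cfg), "per class")
  expect_error(train_config(), "seed")
})

test_that("params survive a JSON round trip, including the reference weights bit-exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  ref <- stt_reference_params()
  save_params(ref, path)
  back <- load_params(path)
  expect_identical(back$hidden_weights, ref$hidden_weights)
  expect_identical(back$hidden_bias, ref$hidden_bias)
  expect_identical(back$output_weights, ref$output_weights)
  expect_identical(back$output_bias, ref$output_bias)
  expect_null(back$input_norm)
  expect_equal(back$class_of_output, ref$class_of_output)

  trained <- train_mlp(separable_features(8), separable_features(8)$group,
                       train_config(seed = 7, max_epochs = 200))
  save_params(trained, path)
  back2 <- load_params(path)
  expect_equal(back2$hidden_weights, trained$hidden_weights, tolerance = 1e-14)
  expect_equal(back2$input_norm$mean, trained$input_norm$mean, tolerance = 1e-14)
  expect_equal(back2$input_norm$sd, trained$input_norm$sd, tolerance = 1e-14)

  # missing input_norm sub-keys are a format error
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$input_norm <- list(mean = c(0, 0, 0, 0))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_params(path), "format error")
  obj$format <- NULL
  obj$input_norm <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_params(path), "missing key")
})

test_that("a model trained on one simulated cohort generalizes to another", {
  # surrogate recovery: default-profile effect sizes, 10+20 train / 15+18 test
  fig <- default_fig
  n_runs <- 50
  aucs <- vapply(seq_len(n_runs), function(r) {
    tr <- simulate_cohort(fig, cohort_spec(10, 20, seed = 40000 + r))
    ft <- cohort_feature_table(tr$traces, fig)
    params <- train_mlp(ft, ft$group, train_config(seed = 50000 + r))
    va <- simulate_cohort(fig, cohort_spec(15, 18, seed = 60000 + r))
    fv <- cohort_feature_table(va$traces, fig)
    auc(score_feature_table(params, fv), fv$group, "lower_is_positive")
  }, numeric(1))
  expect_gte(mean(aucs >= 0.9), 0.9)
})
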