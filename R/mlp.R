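#' Parameters of the 4-3-2 scoring perceptron
#'
#' The scoring network is a 3-layer perceptron: 4 inputs (the STT variables,
#' in the order tracing accuracy, pressure-change sum, pressure-change max,
#' duration), 3 hidden units with hyperbolic-tangent activation, and a
#' softmax pair of output units whose probabilities sum to 1. Each output
#' unit is mapped to a diagnostic class ("patient" / "healthy"); the STT
#' score is 100 times the probability of the healthy unit.
#'
#' @param hidden_weights 3 x 4 matrix; rows are hidden units H1..H3, columns
#'   inputs I1..I4.
#' @param hidden_bias Numeric 3-vector.
#' @param output_weights 2 x 3 matrix; rows are output units O1, O2, columns
#'   hidden units.
#' @param output_bias Numeric 2-vector.
#' @param input_norm `NULL` (normalization unset: the network refuses to
#'   score raw features) or `list(mean = <4-vector>, sd = <4-vector>)` with
#'   all sds > 0.
#' @param class_of_output Named character vector mapping output units to
#'   classes, a bijection onto `c("patient", "healthy")`; default
#'   `c(O1 = "patient", O2 = "healthy")`.
#' @return An object of class `stt_mlp`.
#' @export
mlp_params <- function(hidden_weights, hidden_bias, output_weights,
                       output_bias, input_norm = NULL,
                       class_of_output = c(O1 = "patient", O2 = "healthy")) {
  hidden_weights <- matrix(as.numeric(hidden_weights), 3, 4)
  output_weights <- matrix(as.numeric(output_weights), 2, 3)
  hidden_bias <- as.numeric(hidden_bias)
  output_bias <- as.numeric(output_bias)
  stopifnot(length(hidden_bias) == 3, length(output_bias) == 2,
            all(is.finite(hidden_weights)), all(is.finite(hidden_bias)),
            all(is.finite(output_weights)), all(is.finite(output_bias)))
  if (!setequal(unname(class_of_output), c("patient", "healthy")) ||
      length(class_of_output) != 2 ||
      !setequal(names(class_of_output), c("O1", "O2")))
    stop("'class_of_output' must map O1 and O2 bijectively onto patient/healthy")
  if (!is.null(input_norm)) {
    stopifnot(is.list(input_norm),
              length(input_norm$mean) == 4, length(input_norm$sd) == 4,
              all(is.finite(input_norm$mean)), all(is.finite(input_norm$sd)))
    if (any(input_norm$sd <= 0)) stop("input_norm sds must be > 0")
    input_norm <- list(mean = as.numeric(input_norm$mean),
                       sd = as.numeric(input_norm$sd))
  }
  structure(
    list(hidden_weights = hidden_weights, hidden_bias = hidden_bias,
         output_weights = output_weights, output_bias = output_bias,
         hidden_activation = "tanh", output_activation = "softmax",
         input_norm = input_norm,
         class_of_output = class_of_output[c("O1", "O2")]),
    class = "stt_mlp")
}

#' @export
print.stt_mlp <- function(x, ...) {
  cat("<stt_mlp> 4-3-2 perceptron (tanh hidden, softmax output)\n")
  cat(sprintf("  output classes: O1 = %s, O2 = %s\n",
              x$class_of_output[["O1"]], x$class_of_output[["O2"]]))
  cat(sprintf("  input normalization: %s\n",
              if (is.null(x$input_norm)) "UNSET (required before scoring)"
              else "set (z-score)"))
  invisible(x)
}

#' Published reference weights of the scoring network
#'
#' Returns the published parameter estimates of the original 4-3-2 network
#' exactly as printed. The normalization constants used to standardize the
#' inputs of the original model were never published, so `input_norm` is left
#' unset and the returned network refuses to score raw feature vectors until
#' normalization constants are supplied with [set_input_norm()] (z-scores can
#' be fed directly to [mlp_forward()]).
#'
#' @return An `stt_mlp` with `input_norm = NULL`.
#' @export
stt_reference_params <- function() {
  hw <- cbind(c(-0.089, 1.922, 4.643),   # I1 -> H1..H3
              c(0.720, -1.611, -3.705),  # I2
              c(0.000, -0.469, -0.599),  # I3
              c(1.378, -2.402, -4.015))  # I4
  ow <- cbind(c(-0.641, 0.640),          # H1 -> O1,O2
              c(-1.235, 1.220),          # H2
              c(1.123, -1.120))          # H3
  mlp_params(hidden_weights = hw,
             hidden_bias = c(-0.805, 0.609, 1.315),
             output_weights = ow,
             output_bias = c(0.497, 0.500),
             input_norm = NULL,
             class_of_output = c(O1 = "patient", O2 = "healthy"))
}

#' Set the input normalization of a network
#'
#' @param params An `stt_mlp`.
#' @param mean,sd Numeric 4-vectors of per-variable means and sds (sds > 0),
#'   in the fixed input order.
#' @return The updated `stt_mlp`.
#' @export
set_input_norm <- function(params, mean, sd) {
  stopifnot(inherits(params, "stt_mlp"))
  mlp_params(params$hidden_weights, params$hidden_bias,
             params$output_weights, params$output_bias,
             input_norm = list(mean = mean, sd = sd),
             class_of_output = params$class_of_output)
}

#' z-score a feature vector for the network
#'
#' @param fv An `stt_features` (or anything [feature_matrix()] accepts,
#'   one row).
#' @param params An `stt_mlp` with `input_norm` set.
#' @return Numeric 4-vector of z-scores in the fixed input order.
#' @export
normalize_features <- function(fv, params) {
  stopifnot(inherits(params, "stt_mlp"))
  if (is.null(params$input_norm))
    stop("input normalization is unset; supply it with set_input_norm()")
  v <- drop(feature_matrix(fv))
  (v - params$input_norm$mean) / params$input_norm$sd
}

.softmax_rows <- function(a) {
  a <- a - apply(a, 1, max)
  e <- exp(a)
  e / rowSums(e)
}

#' Forward pass of the scoring network
#'
#' `h = tanh(hidden_bias + hidden_weights %*% z)`, then a softmax over
#' `output_bias + output_weights %*% h`. The two output probabilities sum
#' to 1.
#'
#' @param params An `stt_mlp`.
#' @param z Numeric 4-vector of normalized inputs, or an n x 4 matrix.
#' @return Named probability pair `c(O1 = , O2 = )`, or an n x 2 matrix for
#'   matrix input.
#' @export
mlp_forward <- function(params, z) {
  stopifnot(inherits(params, "stt_mlp"))
  single <- is.null(dim(z))
  zmat <- if (single) matrix(as.numeric(z), 1, 4) else as.matrix(z)
  if (ncol(zmat) != 4) stop("z must have 4 inputs")
  if (any(!is.finite(zmat))) stop("non-finite input to the network")
  h <- tanh(sweep(zmat %*% t(params$hidden_weights), 2, params$hidden_bias, "+"))
  a <- sweep(h %*% t(params$output_weights), 2, params$output_bias, "+")
  p <- .softmax_rows(a)
  colnames(p) <- c("O1", "O2")
  if (single) p[1, ] else p
}

#' STT score of a feature vector
#'
#' 100 times the probability assigned to the output unit mapped to
#' `"healthy"`. Scores range from 0 to 100; scores near 0 indicate the trace
#' resembles the patient group, scores near 100 the healthy group.
#'
#' @param params An `stt_mlp` with `input_norm` and `class_of_output` set.
#' @param fv An `stt_features` (or one-row feature input).
#' @return Score in \[0, 100\].
#' @export
stt_score <- function(params, fv) {
  z <- normalize_features(fv, params)
  p <- mlp_forward(params, z)
  healthy_unit <- names(params$class_of_output)[params$class_of_output == "healthy"]
  100 * unname(p[healthy_unit])
}

#' Score every row of a feature table
#'
#' @param params An `stt_mlp` with normalization set.
#' @param features Feature `data.frame` or list of `stt_features`.
#' @return Numeric vector of STT scores in \[0, 100\].
#' @export
score_feature_table <- function(params, features) {
  stopifnot(inherits(params, "stt_mlp"))
  if (is.null(params$input_norm))
    stop("input normalization is unset; supply it with set_input_norm()")
  X <- feature_matrix(features)
  Z <- sweep(sweep(X, 2, params$input_norm$mean), 2, params$input_norm$sd, "/")
  p <- mlp_forward(params, Z)
  healthy_unit <- which(params$class_of_output == "healthy")
  100 * unname(p[, healthy_unit])
}

#' Training configuration for the scoring network
#'
#' Full-batch gradient descent with momentum on the cross-entropy of the
#' softmax outputs against one-hot labels. Defaults: learning rate 0.1,
#' momentum 0.9, at most 2000 epochs, stopping when the epoch-to-epoch loss
#' decrease falls below 1e-8, initial weights uniform in +/- 0.5.
#'
#' @param seed Integer RNG seed for weight initialization (required).
#' @param learning_rate Positive step size.
#' @param momentum Momentum coefficient in \[0, 1).
#' @param max_epochs Maximum number of full-batch epochs, >= 1.
#' @param loss_tolerance Stop when `|loss[t-1] - loss[t]|` drops below this.
#' @param init_scale Half-width of the uniform weight initialization.
#' @return A `list` of class `stt_train_config`.
#' @export
train_config <- function(seed, learning_rate = 0.1, momentum = 0.9,
                         max_epochs = 2000L, loss_tolerance = 1e-8,
                         init_scale = 0.5) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 1, loss_tolerance >= 0, init_scale > 0)
  structure(list(seed = as.integer(seed),
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 loss_tolerance = loss_tolerance, init_scale = init_scale),
            class = "stt_train_config")
}

# Loss and analytic gradient of the full batch. Z: n x 4 z-scores, Y: n x 2
# one-hot (columns O1 = patient, O2 = healthy). Mean cross-entropy.
.mlp_loss_grad <- function(W1, b1, W2, b2, Z, Y) {
  n <- nrow(Z)
  A1 <- sweep(Z %*% t(W1), 2, b1, "+")
  H <- tanh(A1)
  A2 <- sweep(H %*% t(W2), 2, b2, "+")
  P <- .softmax_rows(A2)
  loss <- -mean(rowSums(Y * log(pmax(P, 1e-300))))
  dA2 <- (P - Y) / n
  gW2 <- t(dA2) %*% H
  gb2 <- colSums(dA2)
  dH <- dA2 %*% W2
  dA1 <- dH * (1 - H^2)
  gW1 <- t(dA1) %*% Z
  gb1 <- colSums(dA1)
  list(loss = loss, gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2)
}

#' Train the scoring network by backpropagation
#'
#' Computes z-score normalization constants from the training set, initializes
#' the weights uniformly from a seeded RNG, and runs full-batch gradient
#' descent with momentum on the cross-entropy loss. The class-to-output
#' mapping of the result is fixed to `O1 = patient`, `O2 = healthy`.
#'
#' @param features Training features: list of `stt_features` or feature
#'   `data.frame`.
#' @param labels Group labels (`"patient"` / `"healthy"` or `"control"`),
#'   at least 2 per class.
#' @param config A [train_config()].
#' @return An `stt_mlp` with `input_norm` set; the attribute `"training"`
#'   records epochs run and initial/final loss.
#' @export
train_mlp <- function(features, labels, config) {
  stopifnot(inherits(config, "stt_train_config"))
  X <- feature_matrix(features)
  g <- normalize_group(labels)
  if (length(g) != nrow(X)) stop("labels and features differ in length")
  counts <- table(factor(g, levels = c("patient", "healthy")))
  if (any(counts < 2))
    stop("need at least 2 examples per class; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))

  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (any(s <= 0))
    stop("a feature is constant on the training set; cannot standardize")
  Z <- sweep(sweep(X, 2, mu), 2, s, "/")
  Y <- cbind(as.numeric(g == "patient"), as.numeric(g == "healthy"))

  set.seed(config$seed)
  is <- config$init_scale
  W1 <- matrix(stats::runif(12, -is, is), 3, 4)
  b1 <- stats::runif(3, -is, is)
  W2 <- matrix(stats::runif(6, -is, is), 2, 3)
  b2 <- stats::runif(2, -is, is)
  vW1 <- matrix(0, 3, 4); vb1 <- numeric(3)
  vW2 <- matrix(0, 2, 3); vb2 <- numeric(2)

  lr <- config$learning_rate; mom <- config$momentum
  loss_prev <- Inf
  initial_loss <- NA_real_; final_loss <- NA_real_; epochs <- 0L
  for (epoch in seq_len(config$max_epochs)) {
    fg <- .mlp_loss_grad(W1, b1, W2, b2, Z, Y)
    if (!is.finite(fg$loss))
      stop(sprintf("non-finite loss at epoch %d", epoch))
    if (epoch == 1L) initial_loss <- fg$loss
    final_loss <- fg$loss
    epochs <- epoch
    if (epoch > 1L && abs(loss_prev - fg$loss) < config$loss_tolerance) break
    loss_prev <- fg$loss
    vW1 <- mom * vW1 - lr * fg$gW1; W1 <- W1 + vW1
    vb1 <- mom * vb1 - lr * fg$gb1; b1 <- b1 + vb1
    vW2 <- mom * vW2 - lr * fg$gW2; W2 <- W2 + vW2
    vb2 <- mom * vb2 - lr * fg$gb2; b2 <- b2 + vb2
  }

  params <- mlp_params(W1, b1, W2, b2,
                       input_norm = list(mean = mu, sd = s),
                       class_of_output = c(O1 = "patient", O2 = "healthy"))
  attr(params, "training") <- list(epochs = epochs,
                                   initial_loss = initial_loss,
                                   final_loss = final_loss,
                                   config = config)
  params
}

#' Save or load network parameters as JSON
#'
#' The schema is versioned under the key `"format": "stt_mlp_v1"`. The round
#' trip is lossless, including normalization constants and the class mapping.
#'
#' @param params An `stt_mlp`.
#' @param path JSON file path.
#' @return `load_params()` returns the `stt_mlp`.
#' @export
save_params <- function(params, path) {
  stopifnot(inherits(params, "stt_mlp"))
  obj <- list(
    format = "stt_mlp_v1",
    hidden_weights = apply(params$hidden_weights, 1, identity, simplify = FALSE),
    hidden_bias = params$hidden_bias,
    output_weights = apply(params$output_weights, 1, identity, simplify = FALSE),
    output_bias = params$output_bias,
    hidden_activation = params$hidden_activation,
    output_activation = params$output_activation,
    input_norm = if (is.null(params$input_norm)) NULL else
      list(mean = params$input_norm$mean, sd = params$input_norm$sd),
    class_of_output = as.list(params$class_of_output))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_params
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("format", "hidden_weights", "hidden_bias", "output_weights",
            "output_bias", "class_of_output")
  miss <- setdiff(need, names(obj))
  if (length(miss))
    stop("format error: missing key(s) ", paste(miss, collapse = ", "))
  if (!identical(obj$format, "stt_mlp_v1"))
    stop("format error: unsupported format '", obj$format, "'")
  hw <- if (is.list(obj$hidden_weights))
    do.call(rbind, obj$hidden_weights) else obj$hidden_weights
  ow <- if (is.list(obj$output_weights))
    do.call(rbind, obj$output_weights) else obj$output_weights
  inorm <- obj$input_norm
  if (!is.null(inorm) && (is.null(inorm$mean) || is.null(inorm$sd)))
    stop("format error: input_norm must contain 'mean' and 'sd'")
  co <- unlist(obj$class_of_output)
  mlp_params(hw, obj$hidden_bias, ow, obj$output_bias,
             input_norm = inorm, class_of_output = co)
}
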