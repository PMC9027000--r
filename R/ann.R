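# Small feed-forward regressors: 3-H-1 multilayer perceptrons and radial
# basis function networks, built from scratch so that every weight, bias and
# scaling bound is inspectable and serializable.

#' Specify a network topology
#'
#' All networks have 3 inputs (water activity, temperature, storage time),
#' one hidden layer and a single linear output neuron; only the hidden-layer
#' size and activation vary.
#'
#' @param type `"mlp"` or `"rbf"`.
#' @param n_hidden Number of hidden neurons (>= 1).
#' @param hidden_activation For MLPs one of `"linear"`, `"logistic"`,
#'   `"exponential"`, `"tanh"`; RBF networks always use `"gaussian"`.
#' @return A `network_spec`.
#' @export
network_spec <- function(type = c("mlp", "rbf"), n_hidden,
                         hidden_activation = if (type == "rbf") "gaussian" else "logistic") {
  type <- match.arg(type)
  n_hidden <- as.integer(n_hidden)
  if (is.na(n_hidden) || n_hidden < 1L) stop("'n_hidden' must be >= 1")
  if (type == "rbf") {
    if (!identical(hidden_activation, "gaussian")) {
      stop("RBF networks use the gaussian hidden activation")
    }
  } else {
    hidden_activation <- match.arg(hidden_activation,
                                   c("linear", "logistic", "exponential", "tanh"))
  }
  structure(list(network_type = type, n_input = 3L, n_hidden = n_hidden,
                 n_output = 1L, hidden_activation = hidden_activation,
                 output_activation = "linear"),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("%s %d-%d-%d network, hidden activation: %s, output: linear\n",
              toupper(x$network_type), x$n_input, x$n_hidden, x$n_output,
              x$hidden_activation))
  invisible(x)
}

#' Hidden-layer activation functions
#'
#' `"exponential"` follows the convention of regression-mode network software
#' where the exponential transfer function is \eqn{e^x} (not a decaying
#' exponential). `"gaussian"` is \eqn{e^{-x^2}}; inside an RBF unit the
#' argument is the scaled distance to the centre, so the unit response is
#' \eqn{\exp(-\|x - c\|^2 / (2\sigma^2))}.
#'
#' @param kind Activation name.
#' @param x Numeric input.
#' @return Transformed values.
#' @export
activation <- function(kind, x) {
  switch(kind,
         linear = x,
         logistic = 1 / (1 + exp(-x)),
         exponential = exp(x),
         tanh = tanh(x),
         gaussian = exp(-x^2),
         stop("unknown activation kind: ", kind))
}

# derivative wrt pre-activation, expressed via the activation value where
# convenient
activation_deriv <- function(kind, x, fx) {
  switch(kind,
         linear = rep(1, length(x)),
         logistic = fx * (1 - fx),
         exponential = fx,
         tanh = 1 - fx^2,
         stop("no gradient for activation kind: ", kind))
}

#' Number of free parameters of an MLP topology
#'
#' Synaptic weights plus biases:
#' \eqn{N_{in} N_h + N_h + N_{out} N_h + N_{out}}.
#'
#' @param spec A `network_spec` (MLP).
#' @return Integer parameter count.
#' @examples
#' count_parameters(network_spec("mlp", 9))  # 46
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  with(spec, n_input * n_hidden + n_hidden + n_output * n_hidden + n_output)
}

#' Rule-of-thumb hidden-layer size
#'
#' Assumes five learning cases per free model parameter:
#' \eqn{N_h = (L - 5 N_{out}) / (5 (N_{in} + 1 + N_{out}))}. The value is
#' generally non-integer; callers round to the neighbouring integers to
#' bracket the recommended layer size.
#'
#' @param L Number of learning cases.
#' @param n_in,n_out Input and output layer sizes.
#' @return The (real-valued) recommended number of hidden neurons.
#' @examples
#' estimate_hidden_nodes(243, 3, 1)  # 9.52, i.e. 9-10 nodes
#' @export
estimate_hidden_nodes <- function(L, n_in = 3, n_out = 1) {
  if (L <= 5 * n_out) stop("'L' must exceed 5 * n_out learning cases")
  (L - 5 * n_out) / (5 * (n_in + 1 + n_out))
}

# ---- min-max scaling ------------------------------------------------------

# bounds: list(x_min, x_max (length 3), y_min, y_max) taken from the
# learning set; degenerate (constant) columns scale to 0.
make_scaling <- function(X, y) {
  list(x_min = apply(X, 2L, min), x_max = apply(X, 2L, max),
       y_min = min(y), y_max = max(y))
}

scale_inputs <- function(X, bounds) {
  rng <- bounds$x_max - bounds$x_min
  rng[rng == 0] <- 1
  sweep(sweep(X, 2L, bounds$x_min), 2L, rng, "/")
}

scale_target <- function(y, bounds) {
  rng <- bounds$y_max - bounds$y_min
  if (rng == 0) rng <- 1
  (y - bounds$y_min) / rng
}

unscale_target <- function(ys, bounds) {
  rng <- bounds$y_max - bounds$y_min
  if (rng == 0) rng <- 1
  ys * rng + bounds$y_min
}

condition_matrix <- function(rows) {
  cbind(aw = rows$water_activity, T = rows$temperature_C, tau = rows$time_days)
}

# ---- forward pass ---------------------------------------------------------

mlp_hidden <- function(net, Xs) {
  Z <- Xs %*% net$hidden_weights + matrix(net$hidden_biases, nrow(Xs),
                                          net$spec$n_hidden, byrow = TRUE)
  activation(net$spec$hidden_activation, Z)
}

rbf_hidden <- function(net, Xs) {
  H <- net$spec$n_hidden
  Phi <- matrix(0, nrow(Xs), H)
  for (h in seq_len(H)) {
    d2 <- rowSums(sweep(Xs, 2L, net$centers[h, ])^2)
    Phi[, h] <- exp(-d2 / (2 * net$widths[h]^2))
  }
  Phi
}

#' Predict phytosterol content with a trained network
#'
#' Inputs are min-max scaled with the bounds stored at training time, passed
#' through the hidden layer and the linear output neuron, and the result is
#' unscaled back to mg g\eqn{^{-1}}. Conditions outside the training bounds
#' are extrapolations: predictions are still returned, with a logical
#' `extrapolated` attribute flagging the affected rows.
#'
#' @param object A `trained_network`.
#' @param newdata Data frame with `water_activity`, `temperature_C`,
#'   `time_days`.
#' @param ... Unused.
#' @return Numeric vector of PS predictions with attribute `extrapolated`.
#' @export
predict.trained_network <- function(object, newdata, ...) {
  X <- condition_matrix(newdata)
  extra <- rowSums(sweep(X, 2L, object$scaling$x_min, "<") |
                   sweep(X, 2L, object$scaling$x_max, ">")) > 0
  Xs <- scale_inputs(X, object$scaling)
  A <- if (object$spec$network_type == "mlp") mlp_hidden(object, Xs) else rbf_hidden(object, Xs)
  ys <- drop(A %*% object$output_weights) + object$output_bias
  structure(unscale_target(ys, object$scaling), extrapolated = extra)
}

#' @export
print.trained_network <- function(x, ...) {
  print(x$spec)
  cat(sprintf("errors (scaled-target MSE): learning %.3g, test %.3g, validation %.3g\n",
              x$errors[["learning"]], x$errors[["test"]], x$errors[["validation"]]))
  cat(sprintf("init seed: %d\n", x$init_seed))
  invisible(x)
}

network_errors <- function(net, learning, test = NULL, validation = NULL) {
  err <- function(rows) {
    if (is.null(rows) || nrow(rows) == 0L) return(NA_real_)
    p <- predict.trained_network(net, rows)
    ys <- scale_target(rows$ps_mg_per_g, net$scaling)
    ps <- scale_target(as.numeric(p), net$scaling)
    mean((ys - ps)^2)
  }
  c(learning = err(learning), test = err(test), validation = err(validation))
}

# ---- JSON round trip ------------------------------------------------------

#' Write / read a trained network as JSON
#'
#' Serializes the topology, every parameter, the scaling bounds, the stored
#' errors and the init seed at full double precision, so a written model
#' reloads to the same predictions.
#'
#' @param net A `trained_network`.
#' @param path File path.
#' @return The reader returns a `trained_network`; the writer returns `path`
#'   invisibly.
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "trained_network"))
  obj <- list(spec = unclass(net$spec),
              scaling = net$scaling,
              output_weights = net$output_weights,
              output_bias = net$output_bias,
              errors = as.list(net$errors),
              init_seed = net$init_seed)
  if (net$spec$network_type == "mlp") {
    obj$hidden_weights <- net$hidden_weights   # 3 x H matrix
    obj$hidden_biases <- net$hidden_biases
  } else {
    obj$centers <- net$centers                 # H x 3 matrix
    obj$widths <- net$widths
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- structure(list(network_type = obj$spec$network_type,
                         n_input = as.integer(obj$spec$n_input),
                         n_hidden = as.integer(obj$spec$n_hidden),
                         n_output = as.integer(obj$spec$n_output),
                         hidden_activation = obj$spec$hidden_activation,
                         output_activation = obj$spec$output_activation),
                    class = "network_spec")
  errors <- vapply(c("learning", "test", "validation"), function(k) {
    v <- obj$errors[[k]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1))
  net <- list(spec = spec,
              scaling = lapply(obj$scaling, as.numeric),
              output_weights = as.numeric(obj$output_weights),
              output_bias = as.numeric(obj$output_bias),
              errors = errors,
              init_seed = as.integer(obj$init_seed))
  if (spec$network_type == "mlp") {
    net$hidden_weights <- matrix(as.numeric(obj$hidden_weights),
                                 spec$n_input, spec$n_hidden)
    net$hidden_biases <- as.numeric(obj$hidden_biases)
  } else {
    net$centers <- matrix(as.numeric(obj$centers), spec$n_hidden, spec$n_input)
    net$widths <- as.numeric(obj$widths)
  }
  structure(net, class = "trained_network")
}
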