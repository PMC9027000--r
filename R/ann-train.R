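# Network training: BFGS for the perceptrons, k-means centres plus a
# regularized linear output layer for the RBF networks.

# parameter vector layout for a 3-H-1 MLP:
# [W (3*H, column-major) | b_hidden (H) | w_out (H) | b_out]
unpack_mlp <- function(theta, H) {
  n_in <- 3L
  W <- matrix(theta[seq_len(n_in * H)], n_in, H)
  b <- theta[n_in * H + seq_len(H)]
  w2 <- theta[n_in * H + H + seq_len(H)]
  b2 <- theta[n_in * H + 2L * H + 1L]
  list(W = W, b = b, w2 = w2, b2 = b2)
}

#' Train a multilayer perceptron by BFGS
#'
#' Inputs and target are min-max scaled to \[0, 1\] using the learning-set
#' bounds; weights are initialized uniformly on \[-0.5, 0.5\] from
#' `init_seed`; BFGS minimizes the mean squared error of the scaled target on
#' the learning rows. The test-set error is monitored at every objective
#' evaluation and the returned parameters are the snapshot with the lowest
#' test error seen (early stopping); without test rows the lowest learning
#' error is kept.
#'
#' @param spec A `network_spec` of type `"mlp"`.
#' @param learning,test,validation Subsets of a `degradation_dataset`
#'   (`test`/`validation` may be `NULL`).
#' @param init_seed Integer seed for weight initialization.
#' @param max_iterations BFGS iteration cap (default 200); 0 returns the
#'   initial random network.
#' @return A `trained_network` with the parameter snapshot, scaling bounds
#'   and the (learning, test, validation) scaled-target MSEs.
#' @export
train_mlp <- function(spec, learning, test = NULL, validation = NULL,
                      init_seed = 1L, max_iterations = 200L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$network_type != "mlp") stop("'spec' must describe an MLP")
  if (is.null(learning) || nrow(learning) == 0L) stop("learning rows are required")

  H <- spec$n_hidden
  act <- spec$hidden_activation
  X <- condition_matrix(learning)
  bounds <- make_scaling(X, learning$ps_mg_per_g)
  Xs <- scale_inputs(X, bounds)
  ys <- scale_target(learning$ps_mg_per_g, bounds)
  has_test <- !is.null(test) && nrow(test) > 0L
  if (has_test) {
    Xt <- scale_inputs(condition_matrix(test), bounds)
    yt <- scale_target(test$ps_mg_per_g, bounds)
  }

  n_par <- count_parameters(spec)
  theta0 <- with_seed(init_seed, stats::runif(n_par, -0.5, 0.5))

  forward_scaled <- function(p, Xm) {
    Z <- Xm %*% p$W + matrix(p$b, nrow(Xm), H, byrow = TRUE)
    A <- activation(act, Z)
    list(Z = Z, A = A, yhat = drop(A %*% p$w2) + p$b2)
  }

  # early-stopping snapshot, updated inside the objective
  snap <- new.env(parent = emptyenv())
  snap$best_theta <- theta0
  snap$best_monitor <- Inf

  objective <- function(theta) {
    p <- unpack_mlp(theta, H)
    fw <- forward_scaled(p, Xs)
    loss <- mean((fw$yhat - ys)^2)
    if (!is.finite(loss)) return(.Machine$double.xmax)
    monitor <- if (has_test) {
      mean((forward_scaled(p, Xt)$yhat - yt)^2)
    } else loss
    if (is.finite(monitor) && monitor < snap$best_monitor) {
      snap$best_monitor <- monitor
      snap$best_theta <- theta
    }
    loss
  }

  gradient <- function(theta) {
    p <- unpack_mlp(theta, H)
    fw <- forward_scaled(p, Xs)
    r <- fw$yhat - ys                       # n
    n <- length(r)
    dA <- outer(r, p$w2)                    # n x H
    dZ <- dA * activation_deriv(act, fw$Z, fw$A)
    gW <- crossprod(Xs, dZ) * (2 / n)       # 3 x H
    gb <- colSums(dZ) * (2 / n)
    gw2 <- colSums(fw$A * r) * (2 / n)
    gb2 <- sum(r) * (2 / n)
    g <- c(as.vector(gW), gb, gw2, gb2)
    g[!is.finite(g)] <- 0
    g
  }

  if (max_iterations > 0L) {
    fit <- tryCatch(
      stats::optim(theta0, objective, gradient, method = "BFGS",
                   control = list(maxit = as.integer(max_iterations))),
      error = function(e) stop(sprintf(
        "MLP training failed (init seed %d): %s", init_seed, conditionMessage(e)))
    )
    objective(fit$par)  # snapshot also considers the final iterate
  } else {
    objective(theta0)
  }

  p <- unpack_mlp(snap$best_theta, H)
  net <- structure(list(spec = spec, scaling = bounds,
                        hidden_weights = p$W, hidden_biases = p$b,
                        output_weights = p$w2, output_bias = p$b2,
                        errors = c(learning = NA_real_, test = NA_real_,
                                   validation = NA_real_),
                        init_seed = as.integer(init_seed)),
                   class = "trained_network")
  net$errors <- network_errors(net, learning, test, validation)
  net
}

#' Train a radial basis function network
#'
#' The hidden layer is placed by k-means on the scaled learning inputs
#' (seeded); each centre's width is the mean Euclidean distance to its
#' `width_neighbors` nearest fellow centres (a single-centre network falls
#' back to the mean distance to the learning points); the linear output layer
#' is solved by ridge-regularized least squares. This is the canonical
#' two-stage RBF fit.
#'
#' @inheritParams train_mlp
#' @param spec A `network_spec` of type `"rbf"`.
#' @param width_neighbors Number of nearest centres entering the width
#'   heuristic (default 2).
#' @param ridge Ridge penalty on the output weights (default 1e-8).
#' @return A `trained_network`.
#' @export
train_rbf <- function(spec, learning, test = NULL, validation = NULL,
                      init_seed = 1L, width_neighbors = 2L, ridge = 1e-8) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$network_type != "rbf") stop("'spec' must describe an RBF network")
  H <- spec$n_hidden
  if (is.null(learning) || nrow(learning) == 0L) stop("learning rows are required")
  if (H > nrow(learning)) {
    stop(sprintf("n_hidden (%d) exceeds the number of learning rows (%d)",
                 H, nrow(learning)))
  }

  X <- condition_matrix(learning)
  bounds <- make_scaling(X, learning$ps_mg_per_g)
  Xs <- scale_inputs(X, bounds)
  ys <- scale_target(learning$ps_mg_per_g, bounds)

  uniq <- unique(Xs)
  k <- min(H, nrow(uniq))
  centers <- if (k == nrow(uniq)) {
    uniq
  } else {
    with_seed(init_seed,
              stats::kmeans(Xs, centers = k, iter.max = 100L, nstart = 1L)$centers)
  }
  if (k < H) {  # duplicate-point degenerate case: pad by recycling centres
    centers <- centers[rep(seq_len(k), length.out = H), , drop = FALSE]
  }
  centers <- matrix(as.numeric(centers), H, ncol(Xs))

  widths <- rbf_widths(centers, Xs, width_neighbors)

  net <- structure(list(spec = spec, scaling = bounds, centers = centers,
                        widths = widths, output_weights = rep(0, H),
                        output_bias = 0,
                        errors = c(learning = NA_real_, test = NA_real_,
                                   validation = NA_real_),
                        init_seed = as.integer(init_seed)),
                   class = "trained_network")
  Phi <- cbind(rbf_hidden(net, Xs), 1)
  A <- crossprod(Phi) + diag(ridge, H + 1L)
  w <- solve(A, crossprod(Phi, ys))
  net$output_weights <- as.numeric(w[seq_len(H)])
  net$output_bias <- as.numeric(w[H + 1L])
  net$errors <- network_errors(net, learning, test, validation)
  net
}

rbf_widths <- function(centers, Xs, width_neighbors) {
  H <- nrow(centers)
  if (H == 1L) {
    d <- sqrt(rowSums(sweep(Xs, 2L, centers[1L, ])^2))
    w <- mean(d)
    return(max(w, 1e-6))
  }
  D <- as.matrix(stats::dist(centers))
  diag(D) <- Inf
  p <- min(width_neighbors, H - 1L)
  widths <- apply(D, 1L, function(row) mean(sort(row)[seq_len(p)]))
  pmax(widths, 1e-6)
}
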