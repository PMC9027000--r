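# Topology grid search with multi-restart training and weighted-error model
# selection.

#' Default MLP / RBF topology grids
#'
#' MLPs: hidden sizes 2--16 crossed with the logistic, exponential and
#' hyperbolic tangent activations (the linear activation can be added but is
#' known to plateau on this problem). RBFs: hidden sizes 2--50 with the
#' gaussian unit.
#'
#' @param hidden Integer vector of hidden-layer sizes.
#' @param activations Character vector of hidden activations (MLP only).
#' @return List of `network_spec` objects.
#' @export
mlp_grid <- function(hidden = 2:16,
                     activations = c("logistic", "tanh", "exponential")) {
  specs <- list()
  for (a in activations) for (h in hidden) {
    specs[[length(specs) + 1L]] <- network_spec("mlp", h, a)
  }
  specs
}

#' @rdname mlp_grid
#' @export
rbf_grid <- function(hidden = 2:50) {
  lapply(hidden, function(h) network_spec("rbf", h))
}

#' Grid search over network topologies
#'
#' Trains `restarts` independently initialized networks per topology (seeds
#' derived as `base_seed + (topology index - 1) * restarts + restart index - 1`),
#' records the per-topology mean learning/test/validation errors (the
#' error-versus-size curves used to judge over- and under-fitting), and
#' selects the single trained network minimizing the weighted error
#' \eqn{w_L E_L + w_T E_T + w_V E_V}, where the weights are the role shares
#' of the dataset (and hence sum to 1). Ties are broken by fewer hidden
#' nodes, then by lower validation error.
#'
#' @param dataset A fully role-assigned `degradation_dataset`.
#' @param grid List of `network_spec` objects (e.g. [mlp_grid()]).
#' @param restarts Networks trained per topology (default 25; the reference
#'   protocol used 1000).
#' @param base_seed Integer master seed for the derived init seeds.
#' @param max_iterations BFGS cap passed to [train_mlp()].
#' @return A `search_result` with elements `curves` (one row per topology:
#'   mean errors over restarts), `best` (the selected `trained_network`),
#'   `weights`, `restarts`, `L` (learning-case count).
#' @export
architecture_search <- function(dataset, grid, restarts = 25L, base_seed = 1L,
                                max_iterations = 200L) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  if (length(grid) == 0L) stop("'grid' must contain at least one topology")
  if (restarts < 1L) stop("'restarts' must be >= 1")
  if (any(dataset$role == "unassigned")) {
    stop("dataset must be fully role-assigned (run split_learning_test first)")
  }

  learning <- dataset[dataset$role == "learning", , drop = FALSE]
  test <- dataset[dataset$role == "test", , drop = FALSE]
  validation <- dataset[dataset$role == "validation", , drop = FALSE]
  w <- set_shares(dataset)

  best <- NULL
  best_key <- c(Inf, Inf, Inf)   # weighted error, n_hidden, validation error
  curves <- vector("list", length(grid))

  for (i in seq_along(grid)) {
    spec <- grid[[i]]
    errs <- matrix(NA_real_, restarts, 3L,
                   dimnames = list(NULL, c("learning", "test", "validation")))
    for (j in seq_len(restarts)) {
      seed <- as.integer(base_seed + (i - 1L) * restarts + (j - 1L))
      net <- if (spec$network_type == "mlp") {
        train_mlp(spec, learning, test, validation, init_seed = seed,
                  max_iterations = max_iterations)
      } else {
        train_rbf(spec, learning, test, validation, init_seed = seed)
      }
      errs[j, ] <- net$errors
      werr <- weighted_error(net$errors, w)
      key <- c(werr, spec$n_hidden, net$errors[["validation"]])
      if (is.finite(werr) && key_less(key, best_key)) {
        best_key <- key
        best <- net
      }
    }
    curves[[i]] <- data.frame(
      network_type = spec$network_type, n_hidden = spec$n_hidden,
      hidden_activation = spec$hidden_activation,
      mean_learning_error = mean(errs[, "learning"]),
      mean_test_error = mean(errs[, "test"]),
      mean_validation_error = mean(errs[, "validation"]),
      stringsAsFactors = FALSE)
  }

  structure(list(curves = do.call(rbind, curves), best = best,
                 weights = w, restarts = as.integer(restarts),
                 L = nrow(learning), base_seed = as.integer(base_seed)),
            class = "search_result")
}

weighted_error <- function(errors, weights) {
  e <- errors[c("learning", "test", "validation")]
  w <- weights[c("learning", "test", "validation")]
  use <- is.finite(e) & w > 0
  sum(w[use] * e[use]) / sum(w[use])
}

# lexicographic comparison with a tolerance-free first key
key_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (is.na(a[k]) || is.na(b[k])) next
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("Topology search: %d topologies x %d restarts (L = %d)\n",
              nrow(x$curves), x$restarts, x$L))
  cat(sprintf("selection weights: learning %.3f, test %.3f, validation %.3f\n",
              x$weights[["learning"]], x$weights[["test"]],
              x$weights[["validation"]]))
  cat("best network:\n")
  print(x$best)
  invisible(x)
}
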