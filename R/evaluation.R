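# Predictive-model validation: goodness-of-fit indices and the elliptical
# joint confidence region (EJCR) test for the predicted-vs-observed line.

#' Validation metrics for predicted vs observed phytosterol content
#'
#' Computes the standard predictive-model validation suite for pairs of
#' experimental (`observed`, \eqn{PS_E}) and model (`predicted`,
#' \eqn{PS_M}) phytosterol levels:
#' \itemize{
#'   \item `R2` = \eqn{1 - SS_{res}/SS_{tot}} about the observed mean (can be
#'     negative for models worse than the mean predictor; not clamped),
#'   \item `MAE` = \eqn{\frac1n \sum |PS_E - PS_M|} (mg g\eqn{^{-1}}),
#'   \item `RMSE` = \eqn{\sqrt{\frac1n \sum (PS_E - PS_M)^2}},
#'   \item `MRPE` = \eqn{\frac{100}{n} \sum (PS_E - PS_M)/PS_E} (signed %;
#'     over-prediction gives negative values),
#'   \item `Bf` (bias factor) = \eqn{10^{\frac1n \sum \log_{10}(PS_M/PS_E)}},
#'   \item `MAPE` = \eqn{\frac{100}{n} \sum |PS_E - PS_M|/PS_E},
#'   \item `Af` (accuracy factor) =
#'     \eqn{10^{\frac1n \sum |\log_{10}(PS_M/PS_E)|}}.
#' }
#' `Bf` and `Af` need strictly positive predictions; if any `predicted` is
#' non-positive they are reported as `NA` with `log_metrics_defined = FALSE`.
#'
#' @param observed Experimental PS values (mg g\eqn{^{-1}}, all > 0).
#' @param predicted Model PS values, same length.
#' @return A `metric_report` (named list of the seven indices plus `n` and
#'   `log_metrics_defined`).
#' @examples
#' m <- compute_metrics(c(5, 6, 7), 1.1 * c(5, 6, 7))
#' m$Bf    # 1.1
#' m$MRPE  # -10
#' @export
compute_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  n <- length(observed)
  if (n < 2L) stop("need at least 2 pairs")
  if (any(observed <= 0)) stop("observed PS values must all be > 0")

  err <- observed - predicted
  log_ok <- all(predicted > 0)
  lr <- if (log_ok) log10(predicted / observed)

  structure(list(
    R2 = 1 - sum(err^2) / sum((observed - mean(observed))^2),
    MAE = mean(abs(err)),
    RMSE = sqrt(mean(err^2)),
    MRPE = mean(err / observed) * 100,
    Bf = if (log_ok) 10^mean(lr) else NA_real_,
    MAPE = mean(abs(err) / observed) * 100,
    Af = if (log_ok) 10^mean(abs(lr)) else NA_real_,
    n = n,
    log_metrics_defined = log_ok
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("n = %d pairs\n", x$n))
  cat(sprintf("  R2 = %.4f  MAE = %.4f  RMSE = %.4f mg/g\n", x$R2, x$MAE, x$RMSE))
  cat(sprintf("  MRPE = %.3f%%  MAPE = %.3f%%  Bf = %.4f  Af = %.4f\n",
              x$MRPE, x$MAPE, x$Bf, x$Af))
  if (!x$log_metrics_defined) {
    cat("  (non-positive predictions: Bf/Af undefined)\n")
  }
  invisible(x)
}

#' Elliptical joint confidence region test
#'
#' Regresses predicted on observed values by ordinary least squares and
#' builds the joint \eqn{(1-\alpha)} confidence region for the (intercept,
#' slope) pair,
#' \deqn{(\beta - \hat\beta)^\top X^\top X (\beta - \hat\beta)
#'   \le 2 s^2 F_{1-\alpha}(2, n-2),}
#' where \eqn{X = [1, PS_E]} and \eqn{s^2} is the residual variance. The
#' model is judged unbiased when the ideal point -- intercept 0, slope 1 --
#' lies inside the ellipse. With zero residual variance the region collapses
#' to a point and the ideal is contained only by exact equality.
#'
#' @param observed,predicted PS pairs as in [compute_metrics()] (n >= 3).
#' @param confidence Confidence level (default 0.95).
#' @return An `ejcr_result` with `intercept`, `slope`, `xtx` (2x2
#'   cross-product matrix), `s2`, `f_critical`, `contains_ideal`, `n`,
#'   `confidence` and `axes` (principal half-axis lengths and directions of
#'   the ellipse, for reporting/plotting).
#' @export
ejcr_test <- function(observed, predicted, confidence = 0.95) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  n <- length(observed)
  if (n < 3L) stop("need at least 3 pairs")
  if (length(unique(observed)) < 2L) {
    stop("observed values are degenerate (all equal): slope is not identifiable")
  }
  X <- cbind(1, observed)
  qx <- qr(X)
  beta <- qr.coef(qx, predicted)
  resid <- predicted - drop(X %*% beta)
  s2 <- sum(resid^2) / (n - 2L)
  fcrit <- stats::qf(confidence, 2L, n - 2L)
  xtx <- crossprod(X)
  d <- c(0, 1) - beta
  lhs <- drop(t(d) %*% xtx %*% d)
  rhs <- 2 * s2 * fcrit

  contains <- if (s2 <= .Machine$double.eps^0.9 * mean(predicted^2 + 1)) {
    # zero-residual limit: the region degenerates to the point estimate
    all(abs(d) < 1e-10)
  } else {
    lhs <= rhs
  }

  ev <- eigen(xtx, symmetric = TRUE)
  axes <- if (rhs > 0) sqrt(rhs / ev$values) else c(0, 0)

  structure(list(intercept = unname(beta[1L]), slope = unname(beta[2L]),
                 xtx = xtx, s2 = s2, f_critical = fcrit,
                 contains_ideal = contains, n = n, confidence = confidence,
                 axes = list(half_lengths = axes, directions = ev$vectors)),
            class = "ejcr_result")
}

#' @export
print.ejcr_result <- function(x, ...) {
  cat(sprintf("EJCR test (%.0f%% confidence, n = %d)\n", 100 * x$confidence, x$n))
  cat(sprintf("  fitted line: predicted = %.4f + %.4f * observed\n",
              x$intercept, x$slope))
  cat(sprintf("  ideal point (intercept 0, slope 1) %s the joint region\n",
              if (x$contains_ideal) "INSIDE" else "OUTSIDE"))
  invisible(x)
}

#' Full per-role evaluation of a model on a dataset
#'
#' Applies [compute_metrics()] and [ejcr_test()] to each data-role subset,
#' following the usual layout: L (learning), T (test), B (building = L + T)
#' and V (validation).
#'
#' @param dataset A role-assigned `degradation_dataset`.
#' @param predict_fun Function mapping a subset of the dataset to predicted
#'   PS values (e.g. `function(rows) predict(fit, rows)`).
#' @param confidence EJCR confidence level.
#' @return Named list (`learning`, `test`, `building`, `validation`), each
#'   with `metrics` and `ejcr` (subsets with < 3 rows are skipped).
#' @export
evaluate_model <- function(dataset, predict_fun, confidence = 0.95) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  subsets <- list(
    learning = dataset$role == "learning",
    test = dataset$role == "test",
    building = dataset$role %in% c("learning", "test"),
    validation = dataset$role == "validation"
  )
  lapply(subsets, function(keep) {
    rows <- dataset[keep, , drop = FALSE]
    if (nrow(rows) < 3L) return(NULL)
    pred <- as.numeric(predict_fun(rows))
    list(metrics = compute_metrics(rows$ps_mg_per_g, pred),
         ejcr = ejcr_test(rows$ps_mg_per_g, pred, confidence))
  })
}
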