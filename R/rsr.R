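# Second-order response-surface regression of phytosterol content on
# water activity, temperature and storage time.

RSR_TERMS <- c("intercept", "aw", "aw2", "T", "T2", "tau", "tau2",
               "aw_T", "aw_tau", "T_tau")

#' Reference response-surface coefficients
#'
#' The published 10-term quadratic surface for the total phytosterol content
#' PS (mg g\eqn{^{-1}}) of bulk-stored rapeseed as a function of seed water
#' activity \eqn{a_w}, temperature \eqn{T} (deg C) and storage time
#' \eqn{\tau} (days):
#' \deqn{PS = \beta_0 + \beta_1 a_w + \beta_2 a_w^2 + \beta_3 T + \beta_4 T^2
#'   + \beta_5 \tau + \beta_6 \tau^2 + \beta_7 a_w T + \beta_8 a_w \tau
#'   + \beta_9 T \tau}
#' Values are stored exactly as printed, to 4 decimal places.
#'
#' @return Named numeric vector of the 10 coefficients, in design-row order.
#' @examples
#' predict_rsr(reference_rsr_coefficients(),
#'             data.frame(water_activity = 0.75, temperature_C = 12,
#'                        time_days = 0))  # about 7.0026 mg/g
#' @export
reference_rsr_coefficients <- function() {
  c(intercept = -55.1677,
    aw        = 132.8619,
    aw2       = -69.4989,
    T         = 0.9326,
    T2        = -0.0037,
    tau       = 0.2277,
    tau2      = 0.0001,
    aw_T      = -1.0046,
    aw_tau    = -0.2870,
    T_tau     = -0.0013)
}

#' Design row of the quadratic surface
#'
#' @param condition Data frame (or one-row list) with `water_activity`,
#'   `temperature_C`, `time_days`.
#' @return Matrix with one row per condition, columns ordered
#'   `[1, aw, aw^2, T, T^2, tau, tau^2, aw*T, aw*tau, T*tau]`.
#' @export
design_row <- function(condition) {
  aw <- condition$water_activity
  tt <- condition$temperature_C
  tau <- condition$time_days
  m <- cbind(1, aw, aw^2, tt, tt^2, tau, tau^2, aw * tt, aw * tau, tt * tau)
  colnames(m) <- RSR_TERMS
  m
}

#' Predict phytosterol content from surface coefficients
#'
#' @param coefficients Named (or ordered) 10-vector of coefficients, see
#'   [reference_rsr_coefficients()] for the term order.
#' @param conditions Data frame with columns `water_activity`,
#'   `temperature_C`, `time_days`.
#' @return Numeric vector of PS predictions in mg g\eqn{^{-1}}. Negative
#'   values are returned as-is; callers decide how to flag them.
#' @export
predict_rsr <- function(coefficients, conditions) {
  beta <- as.numeric(coefficients)
  if (length(beta) != 10L || any(!is.finite(beta))) {
    stop("'coefficients' must be 10 finite values")
  }
  drop(design_row(conditions) %*% beta)
}

#' Fit the quadratic response surface by ordinary least squares
#'
#' Fits the full second-order polynomial (linear, quadratic and two-way
#' interaction terms in \eqn{a_w}, \eqn{T}, \eqn{\tau}) to phytosterol
#' measurements. Predictors are deliberately left on their raw scales so the
#' coefficients are directly comparable with the published reference set; the
#' fit therefore uses a pivoted QR factorization rather than normal
#' equations, because the squared temperature and time columns make the
#' design poorly conditioned.
#'
#' @param dataset A `degradation_dataset`.
#' @param roles Character vector of roles to fit on (default the building
#'   data, i.e. learning + test + unassigned).
#' @return An `rsr_fit` with elements `coefficients`, `standard_errors`,
#'   `p_values` (two-sided t tests on n - 10 df), `residual_standard_error`,
#'   `correlation_R` (Pearson correlation of fitted vs observed), `n`,
#'   `roles`.
#' @export
fit_rsr <- function(dataset, roles = c("learning", "test", "unassigned")) {
  stopifnot(inherits(dataset, "degradation_dataset"))
  rows <- dataset[dataset$role %in% roles, , drop = FALSE]
  n <- nrow(rows)
  if (n < 11L) {
    stop(sprintf("need at least 11 rows to fit the 10-term surface, got %d", n))
  }
  x <- design_row(rows)
  y <- rows$ps_mg_per_g

  qx <- qr(x, LAPACK = FALSE)   # Householder QR with column pivoting
  if (qx$rank < ncol(x)) {
    deficient <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(deficient, collapse = ", "),
         " (the design needs >= 3 levels of each factor)")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(x %*% beta)
  resid <- y - fitted
  df_res <- n - ncol(x)
  s2 <- sum(resid^2) / df_res
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  se <- sqrt(s2 * diag(xtx_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df_res, lower.tail = FALSE)

  structure(list(
    coefficients = stats::setNames(beta, RSR_TERMS),
    standard_errors = stats::setNames(se, RSR_TERMS),
    p_values = stats::setNames(pval, RSR_TERMS),
    residual_standard_error = sqrt(s2),
    correlation_R = if (stats::sd(y) > 0 && stats::sd(fitted) > 0) {
      stats::cor(fitted, y)
    } else NA_real_,   # degenerate (constant) response
    n = n,
    df_residual = df_res,
    roles = roles
  ), class = "rsr_fit")
}

#' @export
print.rsr_fit <- function(x, ...) {
  cat(sprintf("Quadratic response-surface fit (n = %d, residual SE = %.4f, R = %.4f)\n",
              x$n, x$residual_standard_error, x$correlation_R))
  tab <- data.frame(coefficient = sprintf("%.4f", x$coefficients),
                    std_error = sprintf("%.4f", x$standard_errors),
                    p_value = format.pval(x$p_values, digits = 3),
                    row.names = names(x$coefficients))
  print(tab)
  invisible(x)
}

#' @export
predict.rsr_fit <- function(object, newdata, ...) {
  predict_rsr(object$coefficients, newdata)
}

#' Write / read a response-surface fit as JSON
#'
#' @param fit An `rsr_fit`.
#' @param path File path.
#' @return `read_rsr_json` returns an `rsr_fit`; the writer returns `path`
#'   invisibly.
#' @export
write_rsr_json <- function(fit, path) {
  stopifnot(inherits(fit, "rsr_fit"))
  obj <- list(model = "rsr",
              coefficients = as.list(fit$coefficients),
              standard_errors = as.list(fit$standard_errors),
              p_values = as.list(fit$p_values),
              residual_standard_error = fit$residual_standard_error,
              correlation_R = fit$correlation_R,
              n = fit$n, df_residual = fit$df_residual, roles = fit$roles)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       na = "null")
  invisible(path)
}

#' @rdname write_rsr_json
#' @export
read_rsr_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    coefficients = unlist(obj$coefficients),
    standard_errors = unlist(obj$standard_errors),
    p_values = unlist(obj$p_values),
    residual_standard_error = obj$residual_standard_error,
    correlation_R = obj$correlation_R,
    n = obj$n, df_residual = obj$df_residual, roles = obj$roles
  ), class = "rsr_fit")
}
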