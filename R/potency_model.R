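#' Fit a potency-prediction model on log10 scale
#'
#' Regresses log10 potency (composite potency value or a single reference, in
#' ug/cm2 or umol/cm2) on log10 cDV0 (ug/mL or uM). Two families are
#' available: ordinary least squares (`"ols"`) and a Huber robust regression
#' (`"huber"`) fitted by iteratively reweighted least squares, which
#' down-weights observations with large residuals. With `with_slope = FALSE`
#' (the default, and the preferred configuration by AIC on the reference
#' dataset) the slope is fixed at 1 and only the intercept is estimated, so
#' predictions reduce to multiplying cDV0 by the constant `10^intercept`.
#'
#' The Huber IRLS uses weights \eqn{w(r) = \min(1, k s / |r|)} with the scale
#' \eqn{s} re-estimated at every iteration as \eqn{1.4826 \times
#' \mathrm{median}|r|}, and iterates until the largest coefficient change
#' falls below `tol`. The intercept confidence interval is the asymptotic
#' normal interval of the M-estimator.
#'
#' @param data A data frame holding the training chemicals.
#' @param cdv0,potency Unquoted column names of the cDV0 concentrations and
#'   the potency values, both positive and on the original (unlogged) scale.
#'   Rows with a missing value in either column are dropped.
#' @param family `"huber"` (default) or `"ols"`.
#' @param with_slope Estimate a slope (`TRUE`) or fix it at 1 (`FALSE`).
#' @param k Huber tuning constant in scale units; 1.345 gives 95\% efficiency
#'   under Gaussian errors.
#' @param tol,max_iter IRLS convergence tolerance on coefficients and
#'   iteration cap; non-convergence returns the best iterate with a warning.
#' @param basis Optional label (`"mass"` or `"molar"`) recorded on the model.
#' @param conf_level Level for the intercept confidence interval.
#' @return An object of class `potency_model` with `coefficients`
#'   (`intercept`, `slope`), `intercept_ci`, `scale`, `n`, `converged`, the
#'   training log10 values, and metadata. Supports `predict()`, [tidy()],
#'   [glance()], `logLik()` (Gaussian profile, so `AIC()` works) and
#'   `print()`.
#' @examples
#' d <- data.frame(conc = c(1, 2, 4), pod = c(300, 610, 1180))
#' m <- fit_potency_model(d, conc, pod)
#' predict(m, cdv0 = 1)
#' @export
fit_potency_model <- function(data, cdv0, potency,
                              family = c("huber", "ols"),
                              with_slope = FALSE, k = 1.345,
                              tol = 1e-8, max_iter = 50,
                              basis = NULL, conf_level = 0.95) {
  family <- match.arg(family)
  stopifnot(is.data.frame(data), k > 0)
  cv <- rlang::eval_tidy(rlang::enquo(cdv0), data)
  pv <- rlang::eval_tidy(rlang::enquo(potency), data)
  keep <- !is.na(cv) & !is.na(pv)
  cv <- cv[keep]; pv <- pv[keep]
  if (any(cv <= 0) || any(pv <= 0)) {
    stop("cDV0 and potency values must be positive.", call. = FALSE)
  }
  x <- log10(cv); y <- log10(pv)
  n <- length(x)
  n_min <- if (with_slope) 2L else 1L
  if (n < n_min) stop("Too few training chemicals.", call. = FALSE)
  if (with_slope && length(unique(x)) == 1L) {
    stop("Degenerate fit: all cDV0 values identical.", call. = FALSE)
  }

  if (family == "ols") {
    if (with_slope) {
      lmfit <- stats::lm(y ~ x)
      coefs <- c(intercept = unname(stats::coef(lmfit)[1]),
                 slope = unname(stats::coef(lmfit)[2]))
      ici <- unname(stats::confint(lmfit, level = conf_level)[1, ])
      resid <- stats::resid(lmfit)
    } else {
      z <- y - x
      lmfit <- stats::lm(z ~ 1)
      coefs <- c(intercept = mean(z), slope = 1)
      ici <- unname(stats::confint(lmfit, level = conf_level)[1, ])
      resid <- z - mean(z)
    }
    hub <- list(scale = stats::sd(resid), converged = TRUE, iterations = 0L,
                weights = rep(1, n))
  } else {
    hub <- huber_irls(x, y, with_slope = with_slope, k = k,
                      tol = tol, max_iter = max_iter)
    coefs <- hub$coefficients
    ici <- huber_intercept_ci(hub, conf_level)
    resid <- hub$residuals
  }

  structure(
    list(
      family = family, with_slope = with_slope, basis = basis, k = k,
      coefficients = coefs, intercept_ci = ici,
      scale = hub$scale, weights = hub$weights,
      converged = hub$converged, iterations = hub$iterations,
      residuals = resid, x = x, y = y, n = n, conf_level = conf_level
    ),
    class = "potency_model"
  )
}

# Huber M-estimation by IRLS. The design is an intercept column plus,
# optionally, x; with the slope fixed at 1 the response becomes y - x and the
# problem reduces to a robust location estimate of the differences.
huber_irls <- function(x, y, with_slope, k, tol, max_iter) {
  if (with_slope) {
    X <- cbind(1, x); resp <- y
  } else {
    X <- cbind(rep(1, length(x))); resp <- y - x
  }
  beta <- qr.solve(X, resp)  # least-squares start
  converged <- FALSE
  s <- NA_real_
  it <- 0L
  for (it in seq_len(max_iter)) {
    r <- resp - drop(X %*% beta)
    s <- 1.4826 * stats::median(abs(r))
    if (s == 0) { converged <- TRUE; break }  # exact fit
    w <- pmin(1, k * s / abs(r))
    w[abs(r) < .Machine$double.eps] <- 1
    beta_new <- qr.solve(X * sqrt(w), resp * sqrt(w))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  if (!converged) {
    warning("Huber IRLS did not converge in ", max_iter,
            " iterations; returning the last iterate.", call. = FALSE)
  }
  r <- resp - drop(X %*% beta)
  coefs <- if (with_slope) {
    c(intercept = unname(beta[1]), slope = unname(beta[2]))
  } else {
    c(intercept = unname(beta[1]), slope = 1)
  }
  w <- if (s > 0) pmin(1, k * s / pmax(abs(r), .Machine$double.eps)) else rep(1, length(r))
  list(coefficients = coefs, residuals = r, scale = s, weights = w,
       converged = converged, iterations = it,
       X = X, k = k, with_slope = with_slope)
}

# Asymptotic normal interval for the intercept of the Huber M-estimator:
# Var(beta) = s^2 * [sum psi(u)^2 / (n - p)] / [mean psi'(u)]^2 * (X'X)^-1.
huber_intercept_ci <- function(hub, conf_level) {
  r <- hub$residuals; s <- hub$scale; k <- hub$k
  n <- length(r); p <- ncol(hub$X)
  if (!is.finite(s) || s == 0) {
    b <- hub$coefficients[["intercept"]]
    return(c(b, b))
  }
  u <- r / s
  psi <- pmax(pmin(u, k), -k)
  dpsi <- as.numeric(abs(u) <= k)
  v <- s^2 * sum(psi^2) / (n - p) / mean(dpsi)^2
  xtxinv <- solve(crossprod(hub$X))[1, 1]
  se <- sqrt(v * xtxinv)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hub$coefficients[["intercept"]] + c(-1, 1) * z * se
}

#' Predict potency from cDV0
#'
#' Applies the fitted log-linear model: the predicted point of departure is
#' `10^(intercept + slope * log10(cdv0))`. For intercept-only models this is
#' simply `cdv0 * 10^intercept`, so an n-fold difference in cDV0 gives an
#' n-fold difference in the prediction.
#'
#' @param object A `potency_model`.
#' @param cdv0 Positive cDV0 values in the unit the model was trained on
#'   (ug/mL for mass-based, uM for molar-based models).
#' @param ... Unused.
#' @return Predicted potency values (ug/cm2 or umol/cm2).
#' @export
predict.potency_model <- function(object, cdv0, ...) {
  check_positive(cdv0, "cdv0")
  b <- object$coefficients
  10^(b[["intercept"]] + b[["slope"]] * log10(cdv0))
}

#' @export
logLik.potency_model <- function(object, ...) {
  n <- object$n
  rss <- sum(object$residuals^2)
  val <- -n / 2 * (log(2 * pi * rss / n) + 1)
  p <- if (object$with_slope) 2L else 1L
  structure(val, df = p + 1L, nobs = n, class = "logLik")
}

#' @export
print.potency_model <- function(x, ...) {
  lab <- if (x$family == "huber") "Huber robust" else "ordinary least squares"
  cat("Potency model (", lab, ", ",
      if (x$with_slope) "intercept + slope" else "intercept only",
      if (!is.null(x$basis)) paste0(", ", x$basis, " basis"), ")\n", sep = "")
  cat(sprintf("  intercept: %.4f  [%.4f, %.4f]\n", x$coefficients[["intercept"]],
              x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  slope:     %.4f%s\n", x$coefficients[["slope"]],
              if (x$with_slope) "" else " (fixed)"))
  cat(sprintf("  n = %d, residual scale = %.4f\n", x$n, x$scale))
  cat(sprintf("  multiplier: predicted potency = cDV0 x %.4g\n",
              10^x$coefficients[["intercept"]]))
  invisible(x)
}

#' @export
tidy.potency_model <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$coefficients[["intercept"]], x$coefficients[["slope"]]),
    conf.low = c(x$intercept_ci[1], NA_real_),
    conf.high = c(x$intercept_ci[2], NA_real_)
  )
}

#' @export
glance.potency_model <- function(x, ...) {
  tibble::tibble(
    family = x$family, with_slope = x$with_slope,
    basis = if (is.null(x$basis)) NA_character_ else x$basis,
    n = x$n, sigma = x$scale, AIC = stats::AIC(x),
    converged = x$converged
  )
}
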