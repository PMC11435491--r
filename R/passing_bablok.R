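#' Passing-Bablok errors-in-variables regression
#'
#' Fits the nonparametric Passing-Bablok line between two measurements of the
#' same latent quantity. Both axes are assumed error-prone; the estimator is
#' the offset-corrected median of all pairwise slopes
#' \eqn{S_{ij} = (y_j - y_i)/(x_j - x_i)}, which makes the fit robust and
#' (approximately) symmetric in x and y. Pairwise slopes equal to -1 are
#' discarded and the median index is shifted by an offset K; pairs tied in x
#' (infinite slope) or in y (zero slope) contribute to the offset, and for an
#' even slope count the upper median pair is averaged. The intercept is the
#' median of \eqn{y_i - a x_i}.
#'
#' The default 95\% confidence intervals are the classical order-statistic
#' (rank-based) intervals; `ci = "bootstrap"` gives seeded percentile
#' case-resampling intervals instead (see [bootstrap_pb_ci()]).
#'
#' @param data A data frame containing the two measurement columns.
#' @param x,y Column names (unquoted) of the x- and y-axis measurements,
#'   typically already log10-transformed doses. Rows with a missing value in
#'   either column are dropped.
#' @param conf_level Confidence level for the coefficient intervals.
#' @param ci Interval type: `"analytic"` (default), `"bootstrap"` or `"none"`.
#' @param n_boot Number of bootstrap replicates when `ci = "bootstrap"`.
#' @param seed Seed for the bootstrap resampling.
#' @return An object of class `pb_fit` with elements `slope`, `intercept`,
#'   `ci_slope`, `ci_intercept`, `n`, `conf_level`, `ci_method` and the
#'   fitted `data`. Supports [tidy()], [glance()] and `print()`.
#' @examples
#' d <- data.frame(u = 0:3, v = 0:3)
#' fit_passing_bablok(d, u, v)
#' @export
fit_passing_bablok <- function(data, x, y, conf_level = 0.95,
                               ci = c("analytic", "bootstrap", "none"),
                               n_boot = 10000, seed = NULL) {
  ci <- match.arg(ci)
  stopifnot(is.data.frame(data))
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  fit <- pb_fit_core(xv, yv)
  fit$conf_level <- conf_level
  fit$ci_method <- ci
  if (ci == "analytic") {
    cis <- pb_analytic_ci(xv, yv, conf_level)
    fit$ci_slope <- cis$slope
    fit$ci_intercept <- cis$intercept
  } else if (ci == "bootstrap") {
    cis <- bootstrap_pb_ci(xv, yv, n_boot = n_boot, seed = seed,
                           conf_level = conf_level)
    fit$ci_slope <- cis$ci_slope
    fit$ci_intercept <- cis$ci_intercept
    fit$n_boot <- n_boot
  } else {
    fit$ci_slope <- c(NA_real_, NA_real_)
    fit$ci_intercept <- c(NA_real_, NA_real_)
  }
  fit$data <- tibble::tibble(x = xv, y = yv)
  class(fit) <- "pb_fit"
  fit
}

# Pairwise slopes and the tie-aware offset.
#
# Returns the sorted finite slopes S (x-tied pairs excluded, slopes of
# exactly -1 discarded) and the offset K = #{S < -1} + #{tied pairs}. Pairs
# of identical points are ignored entirely.
pb_slope_stats <- function(x, y) {
  n <- length(x)
  lt <- lower.tri(matrix(0, n, n))
  dx <- outer(x, x, "-")[lt]
  dy <- outer(y, y, "-")[lt]
  identical_pt <- dx == 0 & dy == 0
  x_tie <- dx == 0 & dy != 0
  y_tie <- dy == 0 & dx != 0
  S <- dy[!identical_pt & !x_tie] / dx[!identical_pt & !x_tie]
  S <- sort(S[S != -1])
  list(S = S, K = sum(S < -1) + sum(x_tie) + sum(y_tie), n = n)
}

pb_fit_core <- function(x, y) {
  if (length(x) < 3L) {
    stop("Passing-Bablok regression needs at least 3 complete pairs.",
         call. = FALSE)
  }
  if (length(unique(x)) == 1L) {
    stop("Degenerate fit: all x values are identical.", call. = FALSE)
  }
  st <- pb_slope_stats(x, y)
  a <- pb_offset_median(st$S, st$K)
  if (!is.finite(a)) {
    stop("Degenerate fit: the pairwise-slope median is not finite.",
         call. = FALSE)
  }
  list(slope = a, intercept = stats::median(y - a * x), n = st$n)
}

# Offset-corrected median: single order statistic (N + 1)/2 + K for odd N,
# mean of the upper median pair {N/2 + 1 + K, N/2 + 2 + K} for even N.
pb_offset_median <- function(S, K) {
  N <- length(S)
  if (N == 0L) return(NA_real_)
  if (N %% 2 == 1) {
    i <- min(max((N + 1) / 2 + K, 1L), N)
    S[i]
  } else {
    i <- min(max(N / 2 + 1 + K, 1L), N - 1L)
    (S[i] + S[i + 1]) / 2
  }
}

# Rank-based confidence interval for the slope; the intercept interval is
# derived from the slope bounds in the usual way.
pb_analytic_ci <- function(x, y, conf_level) {
  st <- pb_slope_stats(x, y)
  S <- st$S; K <- st$K; N <- length(S); n <- st$n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  M1 <- round((N - C) / 2)
  M2 <- N - M1 + 1
  lo <- S[min(max(M1 + K, 1L), N)]
  hi <- S[min(max(M2 + K, 1L), N)]
  list(slope = c(lo, hi),
       intercept = c(stats::median(y - hi * x), stats::median(y - lo * x)))
}

#' Percentile bootstrap intervals for a Passing-Bablok fit
#'
#' Resamples chemicals (cases) with replacement, refits the Passing-Bablok
#' line on each resample and returns percentile confidence intervals for the
#' slope and intercept. Degenerate resamples (all x identical) are redrawn;
#' their count is recorded in the `n_degenerate` attribute.
#'
#' @param x,y Numeric vectors of paired (log-scale) measurements.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed; required for reproducibility.
#' @param conf_level Confidence level.
#' @return A list with `ci_slope`, `ci_intercept` and the matrix of
#'   replicate coefficients in `replicates`.
#' @export
bootstrap_pb_ci <- function(x, y, n_boot = 10000, seed = NULL,
                            conf_level = 0.95) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stop("Need at least 3 complete pairs.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = 2,
                 dimnames = list(NULL, c("slope", "intercept")))
  n_degenerate <- 0L
  for (b in seq_len(n_boot)) {
    repeat {
      i <- sample.int(n, n, replace = TRUE)
      if (length(unique(x[i])) > 1L) break
      n_degenerate <- n_degenerate + 1L
    }
    f <- pb_fit_core(x[i], y[i])
    reps[b, ] <- c(f$slope, f$intercept)
  }
  alpha <- (1 - conf_level) / 2
  out <- list(
    ci_slope = unname(stats::quantile(reps[, 1], c(alpha, 1 - alpha))),
    ci_intercept = unname(stats::quantile(reps[, 2], c(alpha, 1 - alpha))),
    replicates = reps
  )
  attr(out, "n_degenerate") <- n_degenerate
  out
}

#' Orthogonal projection of points onto a Passing-Bablok line
#'
#' Projects (x, y) points onto the fitted line y = a x + b along the
#' perpendicular direction, returning the foot of the perpendicular:
#' \deqn{\hat x = (x + a (y - b)) / (1 + a^2), \quad \hat y = a \hat x + b.}
#'
#' @param x,y Numeric vectors of point coordinates (log scale).
#' @param fit A `pb_fit` object (or any list with `slope` and `intercept`).
#' @return A tibble with columns `x_hat` and `y_hat`.
#' @export
project_point <- function(x, y, fit) {
  a <- fit$slope; b <- fit$intercept
  if (!is.finite(a) || a == 0) {
    stop("Degenerate projection: slope must be finite and non-zero.",
         call. = FALSE)
  }
  x_hat <- (x + a * (y - b)) / (1 + a^2)
  tibble::tibble(x_hat = x_hat, y_hat = a * x_hat + b)
}

#' Along-line distances between projected points
#'
#' Euclidean distances along the fitted line from the point with the smallest
#' projected x, rescaled by \eqn{1/\sqrt{1 + a^2}} so one unit of distance
#' corresponds to one unit on the original x axis (the slope inflates raw
#' along-line distances by \eqn{\sqrt{1 + a^2}} per x unit).
#'
#' @param projections A data frame with columns `x_hat` and `y_hat`, as
#'   returned by [project_point()].
#' @param fit The `pb_fit` the projections were made onto.
#' @return Numeric vector of non-negative distances; the minimal-x chemical
#'   has distance 0.
#' @export
along_line_distances <- function(projections, fit) {
  stopifnot(all(c("x_hat", "y_hat") %in% names(projections)))
  a <- fit$slope
  xh <- projections$x_hat; yh <- projections$y_hat
  sqrt((xh - min(xh))^2 + (yh - min(yh))^2) / sqrt(1 + a^2)
}

#' @export
print.pb_fit <- function(x, ...) {
  cat("Passing-Bablok regression (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  slope:     %.4f  [%.4f, %.4f]\n",
              x$slope, x$ci_slope[1], x$ci_slope[2]))
  cat(sprintf("  intercept: %.4f  [%.4f, %.4f]\n",
              x$intercept, x$ci_intercept[1], x$ci_intercept[2]))
  cat("  CI method: ", x$ci_method, " (level ", x$conf_level, ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.pb_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$ci_intercept[1], x$ci_slope[1]),
    conf.high = c(x$ci_intercept[2], x$ci_slope[2])
  )
}

#' @export
glance.pb_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, slope = x$slope, intercept = x$intercept,
    conf.level = x$conf_level, ci.method = x$ci_method
  )
}
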