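#' Build a composite potency scale from two in vivo references
#'
#' Constructs a single consensus potency value per chemical from two noisy
#' potency references — the LLNA-derived NESIL and the human HRIPT NOEL —
#' under the assumption that both observe the same latent sensitizing potency
#' with error. A Passing-Bablok line is fitted between the log10 references
#' (human NOEL on x, LLNA NESIL on y), every complete chemical is orthogonally
#' projected onto the line, and its position is measured as the along-line
#' distance from the least potent end, rescaled to original x-axis log units.
#' The distances are then shifted so that the composite scale agrees with the
#' projected coordinates on average:
#' \deqn{shift = (Avg(\hat x) + Avg(\hat y))/2 - Avg(d), \quad
#'       cPV_i = 10^{d_i + shift}.}
#'
#' Chemicals missing either reference receive no composite value but are
#' retained in the output (and can still be scored against whichever
#' reference they have).
#'
#' @param data A chemical table as returned by [read_chemical_table()] or
#'   [chemical_dataset()]: columns `name`, `mw`, `llna_nesil`, `human_noel`
#'   (doses in ug/cm2, `NA` where unavailable).
#' @param basis `"mass"` fits on log10 ug/cm2; `"molar"` first converts both
#'   references to umol/cm2 via the molecular weight.
#' @param ci,n_boot,seed Confidence-interval options passed to
#'   [fit_passing_bablok()].
#' @return An object of class `composite_scale`: a list with the `pb_fit`
#'   in `$fit`, the `basis`, the global `shift`, and `$chemicals`, a tibble
#'   with one row per input chemical carrying the log10 coordinates `x`
#'   (NOEL) and `y` (LLNA), the projections `x_hat`, `y_hat`, the along-line
#'   distance `d` and the composite potency value `cpv` on the original dose
#'   scale (ug/cm2 or umol/cm2). Supports [tidy()], [glance()], `print()`
#'   and [ggplot2::autoplot()].
#' @examples
#' scale <- build_composite_scale(chemical_dataset())
#' glance(scale)
#' @export
build_composite_scale <- function(data, basis = c("mass", "molar"),
                                  ci = "analytic", n_boot = 10000,
                                  seed = NULL) {
  basis <- match.arg(basis)
  stopifnot(is.data.frame(data))
  req <- c("name", "mw", "llna_nesil", "human_noel")
  if (!all(req %in% names(data))) {
    stop("`data` must have columns ", paste(req, collapse = ", "), ".",
         call. = FALSE)
  }
  llna <- data$llna_nesil
  noel <- data$human_noel
  if (basis == "molar") {
    llna <- data$llna_nesil / data$mw
    noel <- data$human_noel / data$mw
  }
  chem <- tibble::tibble(
    name = data$name,
    x = log10(noel),
    y = log10(llna),
    complete = !is.na(llna) & !is.na(noel)
  )
  if (sum(chem$complete) < 3L) {
    stop("Need at least 3 chemicals with both references.", call. = FALSE)
  }
  cc <- chem[chem$complete, ]
  fit <- fit_passing_bablok(cc, x, y, ci = ci, n_boot = n_boot, seed = seed)
  proj <- project_point(cc$x, cc$y, fit)
  d <- along_line_distances(proj, fit)
  shift <- (mean(proj$x_hat) + mean(proj$y_hat)) / 2 - mean(d)

  chem$x_hat <- NA_real_; chem$y_hat <- NA_real_
  chem$d <- NA_real_; chem$cpv <- NA_real_
  chem$x_hat[chem$complete] <- proj$x_hat
  chem$y_hat[chem$complete] <- proj$y_hat
  chem$d[chem$complete] <- d
  chem$cpv[chem$complete] <- 10^(d + shift)

  structure(
    list(fit = fit, basis = basis, shift = shift, chemicals = chem),
    class = "composite_scale"
  )
}

#' @export
print.composite_scale <- function(x, ...) {
  unit <- if (x$basis == "mass") "ug/cm2" else "umol/cm2"
  cat("Composite potency scale (", x$basis, " basis, ", unit, ")\n", sep = "")
  cat(sprintf("  PB line: y = %.4f x + %.4f  (n = %d complete chemicals)\n",
              x$fit$slope, x$fit$intercept, x$fit$n))
  cat(sprintf("  shift: %.4f\n", x$shift))
  rng <- range(x$chemicals$cpv, na.rm = TRUE)
  cat(sprintf("  composite values: %d defined, range %.3g - %.3g %s\n",
              sum(!is.na(x$chemicals$cpv)), rng[1], rng[2], unit))
  invisible(x)
}

#' @export
tidy.composite_scale <- function(x, ...) {
  x$chemicals
}

#' @export
glance.composite_scale <- function(x, ...) {
  tibble::tibble(
    basis = x$basis,
    slope = x$fit$slope,
    intercept = x$fit$intercept,
    shift = x$shift,
    n_complete = sum(x$chemicals$complete),
    n_total = nrow(x$chemicals)
  )
}
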