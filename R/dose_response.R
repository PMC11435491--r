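#' Geometric mean of replicate cDV0 runs
#'
#' Replicate point-of-departure concentrations from repeated assay runs are
#' merged by their geometric mean, which preserves relative (fold-change)
#' differences between runs: the geometric mean of 0.5 and 2 is 1, two-fold
#' from either run.
#'
#' @param values Numeric vector of positive concentrations (ug/mL), one per run.
#' @return A single merged concentration in the same unit.
#' @examples
#' merge_runs(c(0.5, 2))    # 1
#' merge_runs(c(0.737, 1.67))
#' @export
merge_runs <- function(values) {
  if (length(values) < 1L) {
    stop("`values` must contain at least one run.", call. = FALSE)
  }
  if (anyNA(values) || any(values <= 0)) {
    stop("All replicate values must be positive and non-missing.", call. = FALSE)
  }
  exp(mean(log(values)))
}

#' Convert between mass and molar concentration
#'
#' `mass_to_molar()` converts a concentration in ug/mL to uM given the
#' molecular weight in g/mol; `molar_to_mass()` is its inverse.
#'
#' @param conc Positive concentration (ug/mL for `mass_to_molar`, uM for
#'   `molar_to_mass`). Vectorised.
#' @param mw Molecular weight in g/mol (> 0).
#' @return Converted concentration.
#' @export
mass_to_molar <- function(conc, mw) {
  check_positive(conc, "conc")
  check_positive(mw, "mw")
  conc * 1000 / mw
}

#' @rdname mass_to_molar
#' @export
molar_to_mass <- function(conc, mw) {
  check_positive(conc, "conc")
  check_positive(mw, "mw")
  conc * mw / 1000
}

#' Convert between mass and molar dose per area
#'
#' Doses per skin area (ug/cm2, the NESIL unit) convert to umol/cm2 by
#' dividing by the molecular weight; `nesil_molar_to_mass()` inverts.
#'
#' @param dose Positive dose (ug/cm2 or umol/cm2). Vectorised.
#' @param mw Molecular weight in g/mol (> 0).
#' @return Converted dose.
#' @export
nesil_mass_to_molar <- function(dose, mw) {
  check_positive(dose, "dose")
  check_positive(mw, "mw")
  dose / mw
}

#' @rdname nesil_mass_to_molar
#' @export
nesil_molar_to_mass <- function(dose, mw) {
  check_positive(dose, "dose")
  check_positive(mw, "mw")
  dose * mw
}

#' Convert an LLNA EC3 percentage to a NESIL dose
#'
#' The murine local lymph node assay EC3 value (% w/v) maps to a No Expected
#' Sensitization Induction Level in ug/cm2 by the standard factor of 250.
#'
#' @param ec3 Positive EC3 value in percent. Vectorised.
#' @return NESIL in ug/cm2.
#' @export
ec3_to_nesil <- function(ec3) {
  check_positive(ec3, "ec3")
  ec3 * 250
}

check_positive <- function(x, name) {
  if (length(x) < 1L || anyNA(x) || any(x <= 0)) {
    stop("`", name, "` must be positive and non-missing.", call. = FALSE)
  }
  invisible(x)
}

#' Estimate the cDV0 point of departure from a dose-response curve
#'
#' The cDV0 is the lowest tested concentration expected to produce a positive
#' classifier call (decision value, DV, reaching 0). Replicate DVs at each
#' concentration are summarised by their arithmetic mean; scanning
#' concentrations in increasing order, the lowest adjacent pair whose mean DV
#' changes from negative to non-negative brackets the crossing, and cDV0 is
#' the zero of the straight line through the two bracketing points, drawn on
#' either the linear or the log10 concentration axis.
#'
#' A Spearman trend statistic between concentration and mean DV is reported
#' alongside the estimate as a dose-response-relationship check; no hard gate
#' is applied.
#'
#' @param data A data frame with numeric columns `concentration` (ug/mL, > 0)
#'   and `dv` (one row per replicate measurement), and optionally an
#'   `item_id` column identifying separate curves.
#' @param space Interpolation axis: `"linear"` (default) interpolates DV
#'   against concentration, `"log"` against log10 concentration. Dilution
#'   series are geometric, so both are defensible.
#' @return A tibble with one row per curve: `cdv0`, the bracketing
#'   concentrations `bracket_low` and `bracket_high`, `status` (one of
#'   `"estimated"`, `"all_positive"`, `"all_negative"`, `"no_crossing"`),
#'   the number of concentrations `n_conc`, and the Spearman trend
#'   `trend_rho` with its `trend_p`. `status = "all_positive"` means every
#'   mean DV was non-negative, so cDV0 lies below the tested range.
#' @examples
#' curve <- data.frame(concentration = c(0.5, 1, 2, 4),
#'                     dv = c(-0.6, -0.2, 0.2, 0.7))
#' estimate_cdv0(curve)
#' @export
estimate_cdv0 <- function(data, space = c("linear", "log")) {
  space <- match.arg(space)
  stopifnot(is.data.frame(data))
  if (!all(c("concentration", "dv") %in% names(data))) {
    stop("`data` must have columns `concentration` and `dv`.", call. = FALSE)
  }
  if ("item_id" %in% names(data)) {
    out <- dplyr::group_modify(
      dplyr::group_by(data, .data$item_id),
      function(df, key) estimate_cdv0_one(df, space)
    )
    return(dplyr::ungroup(out))
  }
  estimate_cdv0_one(data, space)
}

estimate_cdv0_one <- function(data, space) {
  if (anyNA(data$concentration) || any(data$concentration <= 0)) {
    stop("Concentrations must be positive and non-missing.", call. = FALSE)
  }
  prof <- dplyr::summarise(
    dplyr::group_by(data, concentration = .data$concentration),
    dv = mean(.data$dv), .groups = "drop"
  )
  prof <- dplyr::arrange(prof, .data$concentration)
  conc <- prof$concentration
  dv <- prof$dv
  m <- length(conc)

  trend <- if (m >= 3 && stats::sd(dv) > 0) {
    rank_correlation(conc, dv)
  } else {
    list(estimate = NA_real_, p.value = NA_real_)
  }

  res <- tibble::tibble(
    cdv0 = NA_real_, bracket_low = NA_real_, bracket_high = NA_real_,
    status = NA_character_, n_conc = m,
    trend_rho = trend$estimate, trend_p = trend$p.value
  )

  if (all(dv >= 0)) {
    # the lowest tested concentration is already positive; if its mean DV is
    # exactly 0 the crossing is observed there, otherwise it is below range
    if (dv[1] == 0) {
      res$cdv0 <- conc[1]
      res$bracket_low <- conc[1]
      res$bracket_high <- conc[1]
      res$status <- "estimated"
    } else {
      res$status <- "all_positive"
    }
    return(res)
  }
  if (all(dv < 0)) {
    res$status <- "all_negative"
    return(res)
  }
  cross <- which(dv[-m] < 0 & dv[-1] >= 0)
  if (length(cross) == 0L) {
    res$status <- "no_crossing"
    return(res)
  }
  i <- cross[1]
  c_lo <- conc[i]; c_hi <- conc[i + 1]
  d_lo <- dv[i]; d_hi <- dv[i + 1]
  frac <- -d_lo / (d_hi - d_lo)
  res$cdv0 <- if (space == "linear") {
    c_lo + frac * (c_hi - c_lo)
  } else {
    10^(log10(c_lo) + frac * (log10(c_hi) - log10(c_lo)))
  }
  res$bracket_low <- c_lo
  res$bracket_high <- c_hi
  res$status <- "estimated"
  res
}

# Spearman rho with p from the t transform on n - 2 df
rank_correlation <- function(x, y) {
  r <- stats::cor(x, y, method = "spearman")
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(estimate = r, p.value = 2 * stats::pt(-abs(tt), df = n - 2))
}
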