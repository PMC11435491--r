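#' Simulate a chemical reference table
#'
#' Generates synthetic chemicals with the statistical structure the pipeline
#' assumes: a latent log10 potency drawn uniformly over a range, observed
#' through two lognormally-noised in vivo references, and a cDV0 proportional
#' to the latent potency on the log scale:
#' \deqn{\log_{10} LLNA_i = L_i + N(0, \sigma_{llna}), \quad
#'       \log_{10} NOEL_i = s_{ref} L_i + N(0, \sigma_{noel}), \quad
#'       \log_{10} cDV0_i = L_i - offset + N(0, \sigma_{cdv0}).}
#' With all sigmas zero both references equal the latent potency (for
#' `ref_slope = 1`) and the full pipeline recovers slope 1, intercept 0 and
#' the true offset exactly.
#'
#' @param n_chemicals Number of chemicals.
#' @param log_potency_range Range (lo, hi) of the latent log10 potency in
#'   log10 ug/cm2; the default spans the potency range typical of reference
#'   sensitizer panels.
#' @param sigma_llna,sigma_noel,sigma_cdv0 Noise standard deviations on the
#'   log10 scale.
#' @param true_offset Log10 ratio between latent potency (ug/cm2) and cDV0
#'   (ug/mL); the quantity the intercept-only potency model estimates.
#' @param ref_slope True slope between the two references (1 = both measure
#'   the latent potency on the same scale).
#' @param mw_range Molecular-weight range (g/mol), drawn uniformly.
#' @param n_runs Number of replicate cDV0 runs per chemical (1 or more);
#'   replicate runs scatter around the chemical's cDV0 with `sigma_run`.
#' @param sigma_run Between-run SD on the log10 scale.
#' @param p_missing Probability that a chemical lacks each reference
#'   (independently); creates the missingness pattern of real tables.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A chemical tibble in the same dialect as [chemical_dataset()],
#'   with extra columns `true_log_potency` and `true_cdv0`.
#' @examples
#' sim <- simulate_references(n_chemicals = 10, seed = 1)
#' @export
simulate_references <- function(n_chemicals = 25,
                                log_potency_range = c(1, 4.5),
                                sigma_llna = 0.4, sigma_noel = 0.4,
                                sigma_cdv0 = 0.3, true_offset = 2.5,
                                ref_slope = 1, mw_range = c(100, 400),
                                n_runs = 1, sigma_run = 0.1,
                                p_missing = 0, seed = NULL) {
  stopifnot(n_chemicals >= 1, diff(log_potency_range) >= 0,
            sigma_llna >= 0, sigma_noel >= 0, sigma_cdv0 >= 0,
            diff(mw_range) >= 0, n_runs >= 1, p_missing >= 0, p_missing < 1)
  if (!is.null(seed)) set.seed(seed)
  L <- stats::runif(n_chemicals, log_potency_range[1], log_potency_range[2])
  llna <- 10^(L + stats::rnorm(n_chemicals, 0, sigma_llna))
  noel <- 10^(ref_slope * L + stats::rnorm(n_chemicals, 0, sigma_noel))
  cdv0 <- 10^(L - true_offset + stats::rnorm(n_chemicals, 0, sigma_cdv0))
  mw <- stats::runif(n_chemicals, mw_range[1], mw_range[2])
  runs <- lapply(seq_len(n_chemicals), function(i) {
    if (n_runs == 1) return(cdv0[i])
    # replicate runs whose geometric mean is the chemical's cDV0
    e <- stats::rnorm(n_runs, 0, sigma_run)
    10^(log10(cdv0[i]) + e - mean(e))
  })
  if (p_missing > 0) {
    llna[stats::runif(n_chemicals) < p_missing] <- NA_real_
    noel[stats::runif(n_chemicals) < p_missing] <- NA_real_
  }
  tibble::tibble(
    name = sprintf("chem%02d", seq_len(n_chemicals)),
    cas = sprintf("SYN-%04d", seq_len(n_chemicals)),
    mw = mw,
    cdv0_runs = runs,
    cdv0 = vapply(runs, merge_runs, numeric(1)),
    llna_nesil = llna,
    llna_ns = FALSE,
    human_noel = noel,
    human_loel = NA_real_,
    true_log_potency = L,
    true_cdv0 = cdv0
  )
}

#' Simulate a dose-response decision-value curve
#'
#' Generates replicate decision values over a geometric dilution series for a
#' chemical with a known cDV0. The mean decision value follows
#' \deqn{DV = slope \cdot \log_{10}(c / cDV0) + noise,} so the curve crosses
#' 0 exactly at the true cDV0 and [estimate_cdv0()] with `space = "log"`
#' inverts it exactly in the noiseless case.
#'
#' @param true_cdv0 True crossing concentration (ug/mL, > 0).
#' @param dv_slope Decision-value change per log10 concentration unit.
#' @param dv_noise_sd Replicate noise SD on the decision values.
#' @param top_conc Highest tested concentration; defaults to `8 * true_cdv0`
#'   so the default series brackets the crossing.
#' @param dilution_factor Ratio between consecutive concentrations (in (0,1)).
#' @param n_conc Number of concentrations.
#' @param replicates Replicate decision values per concentration.
#' @param seed Integer seed.
#' @return A tibble with columns `concentration` and `dv`, one row per
#'   replicate measurement, carrying `true_cdv0` and a `bracketed` flag
#'   (whether the true value lies within the tested range) as attributes.
#' @export
simulate_dose_response <- function(true_cdv0, dv_slope = 1,
                                   dv_noise_sd = 0.1, top_conc = NULL,
                                   dilution_factor = 0.5, n_conc = 6,
                                   replicates = 2, seed = NULL) {
  check_positive(true_cdv0, "true_cdv0")
  stopifnot(length(true_cdv0) == 1L, dv_slope > 0,
            dv_noise_sd >= 0, dilution_factor > 0, dilution_factor < 1,
            n_conc >= 2, replicates >= 1)
  if (is.null(top_conc)) top_conc <- 8 * true_cdv0
  if (!is.null(seed)) set.seed(seed)
  conc <- sort(top_conc * dilution_factor^(seq_len(n_conc) - 1))
  bracketed <- true_cdv0 >= min(conc) && true_cdv0 <= max(conc)
  if (!bracketed) {
    warning("true_cdv0 lies outside the tested concentration range; ",
            "the curve will not bracket the crossing.", call. = FALSE)
  }
  out <- tibble::tibble(
    concentration = rep(conc, each = replicates),
    dv = dv_slope * log10(rep(conc, each = replicates) / true_cdv0) +
      stats::rnorm(n_conc * replicates, 0, dv_noise_sd)
  )
  attr(out, "true_cdv0") <- true_cdv0
  attr(out, "bracketed") <- bracketed
  out
}
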