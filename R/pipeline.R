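#' Run the full potency-prediction analysis
#'
#' End-to-end driver reproducing every stage of the analysis on a chemical
#' table: reference correlations (both unit bases, both correlation methods),
#' Passing-Bablok fits, composite potency scales, the four candidate
#' regression models with AIC, final-model coefficients and prediction
#' errors, repeated cross-validation, the paired LLNA-vs-model comparison and
#' the fold-change categorisation.
#'
#' @param data Chemical table; defaults to the bundled [chemical_dataset()].
#' @param repeats,folds Cross-validation design (see [repeated_cv()]).
#' @param seed Integer seed driving every stochastic step.
#' @param cv_roster Roster passed to [repeated_cv()].
#' @return An object of class `potency_analysis`: a list with elements
#'   `correlations`, `pb_fits`, `scales` (mass and molar
#'   [build_composite_scale()] objects), `models` (the four candidate fits
#'   plus `aic` table), `final` (per-chemical predictions and summary
#'   errors), `cv` (a `potency_cv`), `comparison` (paired test of LLNA vs
#'   model errors against NOEL) and `categories`. `print()` gives a compact
#'   summary.
#' @examples
#' \donttest{
#' res <- potency_analysis(repeats = 5, seed = 1)
#' res$final$errors
#' }
#' @export
potency_analysis <- function(data = chemical_dataset(), repeats = 50,
                             folds = 10, seed = 1,
                             cv_roster = c("all", "complete")) {
  cv_roster <- match.arg(cv_roster)

  logs <- tibble::tibble(
    name = data$name,
    cdv0_mass = log10(data$cdv0),
    cdv0_molar = log10(mass_to_molar(data$cdv0, data$mw)),
    llna_mass = log10(data$llna_nesil),
    llna_molar = log10(data$llna_nesil / data$mw),
    noel_mass = log10(data$human_noel),
    noel_molar = log10(data$human_noel / data$mw)
  )

  grid <- expand.grid(
    pair = c("cdv0_vs_llna", "cdv0_vs_noel", "llna_vs_noel"),
    basis = c("molar", "mass"), method = c("pearson", "spearman"),
    stringsAsFactors = FALSE
  )
  correlations <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cols <- switch(g$pair,
      cdv0_vs_llna = c("cdv0", "llna"),
      cdv0_vs_noel = c("cdv0", "noel"),
      llna_vs_noel = c("llna", "noel")
    )
    res <- correlate(logs, !!rlang::sym(paste0(cols[1], "_", g$basis)),
                     !!rlang::sym(paste0(cols[2], "_", g$basis)),
                     method = g$method)
    dplyr::bind_cols(tibble::tibble(pair = g$pair, basis = g$basis), res)
  }))

  scales <- list(
    mass = build_composite_scale(data, basis = "mass"),
    molar = build_composite_scale(data, basis = "molar")
  )
  pb_fits <- list(mass = scales$mass$fit, molar = scales$molar$fit)

  train <- tibble::tibble(
    name = data$name,
    cdv0 = data$cdv0,
    cdv0_molar = mass_to_molar(data$cdv0, data$mw),
    cpv_mass = scales$mass$chemicals$cpv,
    cpv_molar = scales$molar$chemicals$cpv
  )
  cc <- train[!is.na(train$cpv_mass), ]
  models <- list(
    huber_intercept_mass = fit_potency_model(cc, cdv0, cpv_mass,
                                             family = "huber", basis = "mass"),
    huber_intercept_molar = fit_potency_model(cc, cdv0_molar, cpv_molar,
                                              family = "huber", basis = "molar"),
    huber_slope_mass = fit_potency_model(cc, cdv0, cpv_mass, family = "huber",
                                         with_slope = TRUE, basis = "mass"),
    ols_intercept_mass = fit_potency_model(cc, cdv0, cpv_mass, family = "ols",
                                           basis = "mass"),
    ols_slope_mass = fit_potency_model(cc, cdv0, cpv_mass, family = "ols",
                                       with_slope = TRUE, basis = "mass")
  )
  aic <- dplyr::bind_rows(lapply(names(models), function(nm) {
    dplyr::bind_cols(tibble::tibble(model = nm), glance(models[[nm]]))
  }))

  final_model <- models$huber_intercept_mass
  pred <- predict(final_model, data$cdv0)
  per_chemical <- tibble::tibble(
    name = data$name,
    cdv0 = data$cdv0,
    prediction = pred,
    llna_nesil = data$llna_nesil,
    human_noel = data$human_noel,
    cpv = scales$mass$chemicals$cpv,
    vs_llna = fold_changes(pred, data$llna_nesil),
    vs_noel = fold_changes(pred, data$human_noel),
    vs_cpv = fold_changes(pred, scales$mass$chemicals$cpv)
  )
  complete <- !is.na(data$llna_nesil) & !is.na(data$human_noel)
  errors <- tibble::tibble(
    comparison = c("llna_vs_noel_complete", "model_vs_noel_complete",
                   "model_vs_llna_complete", "model_vs_llna_all",
                   "model_vs_noel_all"),
    n = c(sum(complete), sum(complete), sum(complete),
          sum(!is.na(data$llna_nesil)), sum(!is.na(data$human_noel))),
    error = c(
      geo_mean_abs_fold_change(data$llna_nesil[complete],
                               data$human_noel[complete]),
      geo_mean_abs_fold_change(pred[complete], data$human_noel[complete]),
      geo_mean_abs_fold_change(pred[complete], data$llna_nesil[complete]),
      geo_mean_abs_fold_change(pred, data$llna_nesil, na.rm = TRUE),
      geo_mean_abs_fold_change(pred, data$human_noel, na.rm = TRUE)
    )
  )

  cv <- repeated_cv(data, repeats = repeats, folds = folds, seed = seed,
                    basis = "mass", roster = cv_roster)

  comparison <- paired_error_test(
    fold_changes(data$llna_nesil[complete], data$human_noel[complete]),
    fold_changes(pred[complete], data$human_noel[complete])
  )

  categories <- categorize_fold_changes(
    per_chemical[complete, c("name", "vs_llna", "vs_noel", "vs_cpv")]
  )

  structure(
    list(correlations = correlations, pb_fits = pb_fits, scales = scales,
         models = models, aic = aic,
         final = list(model = final_model, per_chemical = per_chemical,
                      errors = errors),
         cv = cv, comparison = comparison, categories = categories,
         config = list(repeats = repeats, folds = folds, seed = seed,
                       cv_roster = cv_roster)),
    class = "potency_analysis"
  )
}

#' @export
print.potency_analysis <- function(x, ...) {
  cat("Potency-prediction analysis\n")
  cat(sprintf("  chemicals: %d (%d with both references)\n",
              nrow(x$final$per_chemical),
              sum(x$scales$mass$chemicals$complete)))
  cat(sprintf("  PB fit (mass):  slope %.3f, intercept %.3f\n",
              x$pb_fits$mass$slope, x$pb_fits$mass$intercept))
  cat(sprintf("  PB fit (molar): slope %.3f, intercept %.3f\n",
              x$pb_fits$molar$slope, x$pb_fits$molar$intercept))
  b <- x$models$huber_intercept_mass$coefficients[["intercept"]]
  bm <- x$models$huber_intercept_molar$coefficients[["intercept"]]
  cat(sprintf("  robust intercepts: mass %.3f (x%.0f), molar %.3f (x%.3f)\n",
              b, 10^b, bm, 10^bm))
  e <- x$final$errors
  cat(sprintf("  final-model errors: %.2f vs LLNA (n=%d), %.2f vs NOEL (n=%d)\n",
              e$error[e$comparison == "model_vs_llna_all"],
              e$n[e$comparison == "model_vs_llna_all"],
              e$error[e$comparison == "model_vs_noel_all"],
              e$n[e$comparison == "model_vs_noel_all"]))
  cat(sprintf("  CV errors (%dx%d): %.2f vs LLNA, %.2f vs NOEL\n",
              x$config$repeats, x$config$folds,
              x$cv$overall_vs_llna, x$cv$overall_vs_noel))
  cat(sprintf("  categories: %d within 3-fold, %d beyond 5-fold (%s)\n",
              x$categories$n_within, x$categories$n_beyond,
              paste(x$categories$flagged, collapse = ", ")))
  invisible(x)
}
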