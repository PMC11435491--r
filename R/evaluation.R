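#' Absolute geometric mean fold change
#'
#' The error metric used throughout the potency evaluation: the exponential
#' of the mean absolute log ratio between predictions and references,
#' \deqn{\exp\left(\sum_i |\ln(pred_i / ref_i)| / n\right).}
#' It is always at least 1, equals 1 only when predictions match references
#' exactly, and is invariant to swapping predictions and references.
#'
#' @param pred,ref Positive dose vectors of equal length.
#' @param na.rm Drop pairs where either value is missing.
#' @return A scalar fold change >= 1.
#' @examples
#' geo_mean_abs_fold_change(c(10, 1000), c(100, 100))  # 10
#' @export
geo_mean_abs_fold_change <- function(pred, ref, na.rm = FALSE) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` must have equal length.", call. = FALSE)
  }
  if (na.rm) {
    keep <- !is.na(pred) & !is.na(ref)
    pred <- pred[keep]; ref <- ref[keep]
  }
  check_positive(pred, "pred")
  check_positive(ref, "ref")
  exp(mean(abs(log(pred / ref))))
}

#' Per-observation fold changes
#'
#' Element-wise absolute fold change `exp(|log(pred/ref)|)`, always >= 1;
#' `NA` where the reference is missing.
#'
#' @inheritParams geo_mean_abs_fold_change
#' @return Numeric vector of fold changes.
#' @export
fold_changes <- function(pred, ref) {
  if (length(pred) != length(ref)) {
    stop("`pred` and `ref` must have equal length.", call. = FALSE)
  }
  check_positive(pred, "pred")
  if (any(!is.na(ref) & ref <= 0)) {
    stop("`ref` must be positive where present.", call. = FALSE)
  }
  exp(abs(log(pred / ref)))
}

#' Pearson or Spearman correlation with t-based p-value
#'
#' Thin wrapper around [stats::cor()] returning the coefficient together with
#' a p-value from the t transform on n - 2 degrees of freedom (used for both
#' methods). Callers are expected to pass log10-transformed doses or
#' concentrations; rows with a missing value in either column are dropped.
#'
#' @param data A data frame.
#' @param x,y Unquoted column names.
#' @param method `"pearson"` or `"spearman"`.
#' @return A one-row tibble: `method`, `estimate`, `statistic`, `p.value`, `n`.
#' @export
correlate <- function(data, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  xv <- rlang::eval_tidy(rlang::enquo(x), data)
  yv <- rlang::eval_tidy(rlang::enquo(y), data)
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3L) stop("Need at least 3 complete pairs.", call. = FALSE)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("Correlation undefined: zero variance.", call. = FALSE)
  }
  r <- stats::cor(xv, yv, method = method)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  tibble::tibble(
    method = method, estimate = r, statistic = tt,
    p.value = 2 * stats::pt(-abs(tt), df = n - 2), n = n
  )
}

#' Repeated k-fold cross-validation of a potency model
#'
#' Evaluates the cDV0-based potency model by repeated cross-validation. In
#' every repeat the chemicals are randomly partitioned into near-equal folds;
#' for each fold the configured model is fitted on the training chemicals
#' that carry a composite potency value and used to predict the held-out
#' chemicals from their cDV0. The held-out predictions of a repeat are scored
#' with [geo_mean_abs_fold_change()] against the LLNA-derived NESILs and the
#' human NOELs (each over the chemicals where that reference exists), and the
#' per-repeat errors are averaged arithmetically across repeats
#' (`aggregate = "geometric"` averages their logs instead).
#'
#' With `roster = "all"` (default) every chemical in `data` is partitioned
#' and scored, so the error rosters match the final-model evaluation; with
#' `roster = "complete"` only chemicals holding both references participate.
#'
#' @param data A chemical table (see [chemical_dataset()]) with columns
#'   `name`, `mw`, `cdv0`, `llna_nesil`, `human_noel`.
#' @param repeats,folds Cross-validation design; defaults 50 and 10.
#' @param seed Integer seed making folds and results reproducible.
#' @param family,with_slope,k Model configuration, see [fit_potency_model()].
#' @param basis `"mass"` or `"molar"`; composite values and cDV0 are
#'   converted accordingly before fitting.
#' @param roster Which chemicals enter the fold partition (see above).
#' @param aggregate Across-repeat summary: `"arithmetic"` (default) or
#'   `"geometric"` mean of the per-repeat errors.
#' @return An object of class `potency_cv`: `per_repeat` (tibble with columns
#'   `repeat_id`, `error_vs_llna`, `error_vs_noel`), `overall_vs_llna`,
#'   `overall_vs_noel`, `fold_assignments` (tibble `repeat_id`, `name`,
#'   `fold`) and the configuration. Supports [tidy()], [glance()], `print()`.
#' @examples
#' cv <- repeated_cv(chemical_dataset(), repeats = 2, folds = 5, seed = 1)
#' glance(cv)
#' @export
repeated_cv <- function(data, repeats = 50, folds = 10, seed = NULL,
                        family = "huber", with_slope = FALSE, k = 1.345,
                        basis = c("mass", "molar"),
                        roster = c("all", "complete"),
                        aggregate = c("arithmetic", "geometric")) {
  basis <- match.arg(basis)
  roster <- match.arg(roster)
  aggregate <- match.arg(aggregate)
  stopifnot(repeats >= 1, folds >= 2)

  scale <- build_composite_scale(data, basis = basis, ci = "none")
  d <- tibble::tibble(
    name = data$name,
    cdv0 = if (basis == "molar") mass_to_molar(data$cdv0, data$mw) else data$cdv0,
    llna = if (basis == "molar") data$llna_nesil / data$mw else data$llna_nesil,
    noel = if (basis == "molar") data$human_noel / data$mw else data$human_noel,
    cpv = scale$chemicals$cpv
  )
  if (roster == "complete") d <- d[!is.na(d$cpv), ]
  n <- nrow(d)
  if (folds > n) stop("`folds` cannot exceed the number of chemicals.",
                      call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  per_repeat <- tibble::tibble(
    repeat_id = seq_len(repeats),
    error_vs_llna = NA_real_, error_vs_noel = NA_real_
  )
  assignments <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    fold <- sample(rep(seq_len(folds), length.out = n))
    pred <- rep(NA_real_, n)
    for (f in seq_len(folds)) {
      train <- fold != f & !is.na(d$cpv)
      if (!any(train)) {
        stop("A training fold contains no chemical with a composite value.",
             call. = FALSE)
      }
      m <- fit_potency_model(d[train, ], cdv0, cpv, family = family,
                             with_slope = with_slope, k = k)
      pred[fold == f] <- predict(m, d$cdv0[fold == f])
    }
    per_repeat$error_vs_llna[rep_i] <-
      geo_mean_abs_fold_change(pred, d$llna, na.rm = TRUE)
    per_repeat$error_vs_noel[rep_i] <-
      geo_mean_abs_fold_change(pred, d$noel, na.rm = TRUE)
    assignments[[rep_i]] <- tibble::tibble(
      repeat_id = rep_i, name = d$name, fold = fold
    )
  }
  agg <- if (aggregate == "arithmetic") mean else function(v) exp(mean(log(v)))
  structure(
    list(
      per_repeat = per_repeat,
      overall_vs_llna = agg(per_repeat$error_vs_llna),
      overall_vs_noel = agg(per_repeat$error_vs_noel),
      fold_assignments = dplyr::bind_rows(assignments),
      config = list(repeats = repeats, folds = folds, seed = seed,
                    family = family, with_slope = with_slope, k = k,
                    basis = basis, roster = roster, aggregate = aggregate,
                    n = n)
    ),
    class = "potency_cv"
  )
}

#' @export
print.potency_cv <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Repeated cross-validation: %d repeats x %d folds (%s, %s%s, n = %d)\n",
              cfg$repeats, cfg$folds, cfg$family,
              if (cfg$with_slope) "intercept + slope" else "intercept only",
              paste0(", ", cfg$basis), cfg$n))
  cat(sprintf("  fold-change error vs LLNA NESIL: %.3f\n", x$overall_vs_llna))
  cat(sprintf("  fold-change error vs human NOEL: %.3f\n", x$overall_vs_noel))
  invisible(x)
}

#' @export
tidy.potency_cv <- function(x, ...) {
  x$per_repeat
}

#' @export
glance.potency_cv <- function(x, ...) {
  tibble::tibble(
    overall_vs_llna = x$overall_vs_llna,
    overall_vs_noel = x$overall_vs_noel,
    repeats = x$config$repeats, folds = x$config$folds,
    family = x$config$family, with_slope = x$config$with_slope,
    basis = x$config$basis, n = x$config$n
  )
}

#' Paired comparison of two fold-change error vectors
#'
#' Two-sided Wilcoxon signed-rank test on the paired absolute log errors,
#' used to ask whether one potency predictor has systematically different
#' errors than another on the same chemicals. Delegates to
#' [stats::wilcox.test()] (exact distribution when sample size permits and no
#' ties are present, normal approximation otherwise).
#'
#' @param errors_a,errors_b Paired fold-change errors (each >= 1) of the two
#'   predictors on the same chemicals.
#' @return A one-row tibble with `statistic`, `p.value`, `n` and `method`.
#' @export
paired_error_test <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b)) {
    stop("Error vectors must be paired (equal length).", call. = FALSE)
  }
  check_positive(errors_a, "errors_a")
  check_positive(errors_b, "errors_b")
  a <- abs(log(errors_a)); b <- abs(log(errors_b))
  if (all(a == b)) {
    return(tibble::tibble(statistic = NA_real_, p.value = 1,
                          n = length(a), method = "wilcoxon signed-rank"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            alternative = "two.sided"))
  tibble::tibble(statistic = unname(ht$statistic), p.value = ht$p.value,
                 n = length(a), method = "wilcoxon signed-rank")
}

#' Categorise chemicals by their prediction fold changes
#'
#' Flags chemicals as consistently well predicted or clearly mispredicted:
#' a chemical is *within* the lower threshold when its largest fold-change
#' error across the available references is below `within` (default 3), and
#' *beyond* the upper threshold when its smallest error across references
#' exceeds `beyond` (default 5). Comparisons are strict, so an error exactly
#' at a boundary falls in neither category.
#'
#' @param errors A data frame with a `name` column and one or more numeric
#'   error columns (e.g. `vs_llna`, `vs_noel`, `vs_cpv`), `NA` where a
#'   reference is unavailable. Chemicals with no available reference are
#'   dropped.
#' @param within,beyond Fold-change thresholds.
#' @return An object of class `fold_change_categories`: a list with `table`
#'   (per-chemical tibble adding `max_error`, `min_error`, `category`),
#'   counts `n_within` and `n_beyond`, and `flagged` (names of the beyond-
#'   threshold chemicals). Supports [tidy()] and `print()`.
#' @export
categorize_fold_changes <- function(errors, within = 3, beyond = 5) {
  stopifnot(is.data.frame(errors), "name" %in% names(errors))
  vals <- as.matrix(errors[setdiff(names(errors), "name")])
  if (ncol(vals) < 1L) stop("No error columns found.", call. = FALSE)
  has_ref <- rowSums(!is.na(vals)) > 0
  errors <- errors[has_ref, ]
  vals <- vals[has_ref, , drop = FALSE]
  max_e <- apply(vals, 1, max, na.rm = TRUE)
  min_e <- apply(vals, 1, min, na.rm = TRUE)
  category <- dplyr::case_when(
    max_e < within ~ paste0("within_", within),
    min_e > beyond ~ paste0("beyond_", beyond),
    TRUE ~ "intermediate"
  )
  table <- dplyr::bind_cols(
    tibble::as_tibble(errors),
    tibble::tibble(max_error = max_e, min_error = min_e, category = category)
  )
  structure(
    list(table = table,
         n_within = sum(max_e < within),
         n_beyond = sum(min_e > beyond),
         flagged = table$name[min_e > beyond],
         within = within, beyond = beyond),
    class = "fold_change_categories"
  )
}

#' @export
print.fold_change_categories <- function(x, ...) {
  cat(sprintf("Fold-change categories over %d chemicals:\n", nrow(x$table)))
  cat(sprintf("  within %g-fold of every available reference: %d\n",
              x$within, x$n_within))
  cat(sprintf("  beyond %g-fold of every available reference: %d (%s)\n",
              x$beyond, x$n_beyond, paste(x$flagged, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.fold_change_categories <- function(x, ...) {
  x$table
}
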