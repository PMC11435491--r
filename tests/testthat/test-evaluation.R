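test_that("the geometric mean fold change has its defining properties", {
  expect_equal(geo_mean_abs_fold_change(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(geo_mean_abs_fold_change(10, 100), 10)
  expect_equal(geo_mean_abs_fold_change(1000, 100), 10)

  set.seed(9)
  for (i in 1:15) {
    n <- sample(2:20, 1)
    p <- 10^runif(n, -1, 3); r <- 10^runif(n, -1, 3)
    e <- geo_mean_abs_fold_change(p, r)
    expect_gte(e, 1)
    expect_equal(e, geo_mean_abs_fold_change(r, p), tolerance = 1e-12)
    expect_equal(e, exp(mean(abs(log(p / r)))), tolerance = 1e-12)
  }
  # 1 only when predictions equal references elementwise
  expect_gt(geo_mean_abs_fold_change(c(10, 1000), c(100, 100)), 1)
  expect_error(geo_mean_abs_fold_change(c(1, -1), c(1, 1)), "positive")
  expect_error(geo_mean_abs_fold_change(1:3, 1:2), "equal length")
  expect_equal(geo_mean_abs_fold_change(c(1, 2), c(1, NA), na.rm = TRUE), 1)
})

test_that("reference-table agreement statistics match the published values", {
  d <- chemical_dataset()
  cc <- d[!is.na(d$llna_nesil) & !is.na(d$human_noel), ]
  expect_equal(geo_mean_abs_fold_change(cc$llna_nesil, cc$human_noel), 2.63,
               tolerance = 0.002)
  cs <- build_composite_scale(d)
  tr <- tibble::tibble(cdv0 = cc$cdv0,
                       cpv = cs$chemicals$cpv[cs$chemicals$complete])
  m <- fit_potency_model(tr, cdv0, cpv, family = "huber")
  pred <- predict(m, cc$cdv0)
  expect_equal(geo_mean_abs_fold_change(pred, cc$human_noel), 2.94,
               tolerance = 0.002)
})

test_that("correlate agrees with brute-force formulas and the published Table", {
  d <- data.frame(x = 1:6)
  d$y <- 2 * d$x + 1
  expect_equal(correlate(d, x, y)$estimate, 1)

  set.seed(10)
  for (i in 1:10) {
    dd <- data.frame(x = rnorm(10), y = rnorm(10))
    expect_equal(correlate(dd, x, y)$estimate, oracle_pearson(dd$x, dd$y),
                 tolerance = 1e-12)
    expect_equal(correlate(dd, x, y, method = "spearman")$estimate,
                 oracle_spearman(dd$x, dd$y), tolerance = 1e-12)
  }
  # p-value via the t transform
  dd <- data.frame(x = rnorm(12)); dd$y <- dd$x + rnorm(12, 0, 0.6)
  ct <- cor.test(dd$x, dd$y)
  expect_equal(correlate(dd, x, y)$p.value, ct$p.value, tolerance = 1e-12)

  chem <- chemical_dataset()
  logs <- tibble::tibble(
    cdv0 = log10(mass_to_molar(chem$cdv0, chem$mw)),
    llna = log10(chem$llna_nesil / chem$mw)
  )
  r <- correlate(logs, cdv0, llna)
  expect_equal(r$n, 29)  # the LLNA non-sensitizer is excluded
  expect_equal(r$estimate, 0.787, tolerance = 0.002)

  expect_error(correlate(data.frame(x = c(1, 1, 1), y = 1:3), x, y), "variance")
  expect_error(correlate(data.frame(x = 1:2, y = 1:2), x, y), "at least 3")
})

test_that("repeated cross-validation is reproducible and partitions correctly", {
  d <- chemical_dataset()
  cv1 <- repeated_cv(d, repeats = 3, folds = 10, seed = 5)
  cv2 <- repeated_cv(d, repeats = 3, folds = 10, seed = 5)
  expect_identical(cv1$per_repeat, cv2$per_repeat)
  expect_identical(cv1$overall_vs_llna, cv2$overall_vs_llna)

  fa <- cv1$fold_assignments
  for (r in unique(fa$repeat_id)) {
    fr <- fa[fa$repeat_id == r, ]
    expect_setequal(fr$name, d$name)          # every chemical exactly once
    expect_equal(nrow(fr), nrow(d))
    sizes <- table(fr$fold)
    expect_lte(diff(range(sizes)), 1)          # near-equal folds
  }
  expect_true(all(cv1$per_repeat$error_vs_llna >= 1))
  expect_error(repeated_cv(d, repeats = 1, folds = 40, seed = 1),
               "cannot exceed")
})

test_that("cross-validation error approaches 1 as the synthetic noise vanishes", {
  sim0 <- simulate_references(n_chemicals = 20, sigma_llna = 0,
                              sigma_noel = 0, sigma_cdv0 = 0, seed = 6)
  cv0 <- repeated_cv(sim0, repeats = 3, folds = 5, seed = 6)
  expect_equal(cv0$overall_vs_llna, 1, tolerance = 1e-9)
  expect_equal(cv0$overall_vs_noel, 1, tolerance = 1e-9)

  sim1 <- simulate_references(n_chemicals = 20, sigma_llna = 0.2,
                              sigma_noel = 0.2, sigma_cdv0 = 0.15, seed = 6)
  cv1 <- repeated_cv(sim1, repeats = 3, folds = 5, seed = 6)
  expect_gt(cv1$overall_vs_llna, cv0$overall_vs_llna)
})

test_that("seed changes move the cross-validation estimate only within noise", {
  d <- chemical_dataset()
  e1 <- glance(repeated_cv(d, repeats = 10, folds = 10, seed = 1))
  e2 <- glance(repeated_cv(d, repeats = 10, folds = 10, seed = 2))
  expect_lt(abs(e1$overall_vs_llna - e2$overall_vs_llna), 0.1)
  expect_lt(abs(e1$overall_vs_noel - e2$overall_vs_noel), 0.1)
})

test_that("the paired error test matches exhaustive sign enumeration", {
  a <- c(2, 2, 2); b <- c(2, 2, 2)
  expect_equal(paired_error_test(a, b)$p.value, 1)

  set.seed(13)
  for (i in 1:5) {
    ea <- exp(abs(rnorm(5, 0, 0.8)))
    eb <- exp(abs(rnorm(5, 0.3, 0.8)))
    p_pkg <- paired_error_test(ea, eb)$p.value
    p_ora <- oracle_wilcoxon_exact(abs(log(ea)) - abs(log(eb)))
    expect_equal(p_pkg, p_ora, tolerance = 1e-12)
  }
  expect_error(paired_error_test(1:3, 1:2), "paired")
})

test_that("LLNA and the final model predict human NOELs comparably", {
  d <- chemical_dataset()
  cc <- d[!is.na(d$llna_nesil) & !is.na(d$human_noel), ]
  cs <- build_composite_scale(d)
  tr <- tibble::tibble(cdv0 = cc$cdv0,
                       cpv = cs$chemicals$cpv[cs$chemicals$complete])
  m <- fit_potency_model(tr, cdv0, cpv, family = "huber")
  p <- paired_error_test(
    fold_changes(cc$llna_nesil, cc$human_noel),
    fold_changes(predict(m, cc$cdv0), cc$human_noel)
  )
  expect_equal(p$p.value, 0.508, tolerance = 0.05)
})

test_that("fold-change categories apply strict thresholds over available references", {
  all_one <- tibble::tibble(name = letters[1:4], vs_llna = rep(1, 4),
                            vs_noel = rep(1, 4))
  cat0 <- categorize_fold_changes(all_one)
  expect_equal(cat0$n_within, 4)
  expect_equal(cat0$n_beyond, 0)

  tb <- tibble::tibble(
    name = c("at_boundary", "good", "bad", "mixed", "one_ref_bad"),
    vs_llna = c(3, 1.5, 8, 2, NA),
    vs_noel = c(2, 2.2, 9, 6, 7)
  )
  ct <- categorize_fold_changes(tb)
  expect_equal(ct$n_within, 1)           # exactly 3 is excluded (strict)
  expect_equal(ct$flagged, c("bad", "one_ref_bad"))
  expect_equal(ct$table$category[ct$table$name == "mixed"], "intermediate")
})

test_that("intercept-only predictions preserve correlations with references", {
  d <- chemical_dataset()
  keep <- !is.na(d$llna_nesil)
  logs <- tibble::tibble(cdv0 = log10(d$cdv0[keep]),
                         llna = log10(d$llna_nesil[keep]),
                         pred = log10(d$cdv0[keep] * 304))
  r_cdv0 <- correlate(logs, cdv0, llna)$estimate
  r_pred <- correlate(logs, pred, llna)$estimate
  expect_equal(r_pred, r_cdv0, tolerance = 1e-12)
})
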