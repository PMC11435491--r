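training_table <- function() {
  d <- chemical_dataset()
  cs <- build_composite_scale(d)
  cs_m <- build_composite_scale(d, basis = "molar")
  tibble::tibble(
    cdv0 = d$cdv0,
    cdv0_molar = mass_to_molar(d$cdv0, d$mw),
    cpv = cs$chemicals$cpv,
    cpv_molar = cs_m$chemicals$cpv
  )[cs$chemicals$complete, ]
}

test_that("exact log-linear data are fitted exactly by both families", {
  d <- data.frame(c0 = c(1, 2, 4, 8), pod = 100 * c(1, 2, 4, 8))
  for (fam in c("ols", "huber")) {
    # lm's confint warns about the zero-residual fit; the warning is benign
    m <- suppressWarnings(fit_potency_model(d, c0, pod, family = fam))
    expect_equal(m$coefficients[["intercept"]], 2, tolerance = 1e-9)
    expect_equal(m$coefficients[["slope"]], 1)
    ms <- suppressWarnings(
      fit_potency_model(d, c0, pod, family = fam, with_slope = TRUE)
    )
    expect_equal(ms$coefficients[["slope"]], 1, tolerance = 1e-9)
    expect_equal(ms$coefficients[["intercept"]], 2, tolerance = 1e-9)
  }
})

test_that("ordinary least squares matches the normal equations", {
  set.seed(8)
  d <- data.frame(c0 = 10^runif(12, -1, 2))
  d$pod <- 10^(2 + 0.8 * log10(d$c0) + rnorm(12, 0, 0.3))
  m <- fit_potency_model(d, c0, pod, family = "ols", with_slope = TRUE)
  x <- log10(d$c0); y <- log10(d$pod)
  slope_ne <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(m$coefficients[["slope"]], slope_ne, tolerance = 1e-12)
  expect_equal(m$coefficients[["intercept"]], mean(y) - slope_ne * mean(x),
               tolerance = 1e-12)
  m0 <- fit_potency_model(d, c0, pod, family = "ols")
  expect_equal(m0$coefficients[["intercept"]], mean(y - x), tolerance = 1e-12)
})

test_that("Huber IRLS equals least squares when no residual is outlying", {
  d <- data.frame(c0 = c(1, 2, 4, 8, 16))
  d$pod <- 10^(2.5 + log10(d$c0) + c(-0.01, 0.01, 0, 0.012, -0.012))
  mh <- fit_potency_model(d, c0, pod, family = "huber")
  mo <- fit_potency_model(d, c0, pod, family = "ols")
  expect_equal(mh$coefficients[["intercept"]],
               mo$coefficients[["intercept"]], tolerance = 1e-6)
  expect_true(all(mh$weights == 1))
})

test_that("Huber converges to least squares as k grows", {
  set.seed(15)
  d <- data.frame(c0 = 10^runif(15, -1, 2))
  d$pod <- 10^(2 + log10(d$c0) + rnorm(15, 0, 0.4))
  d$pod[3] <- d$pod[3] * 500  # gross outlier
  mo <- fit_potency_model(d, c0, pod, family = "ols")
  mk <- fit_potency_model(d, c0, pod, family = "huber", k = 1e6)
  expect_equal(mk$coefficients[["intercept"]],
               mo$coefficients[["intercept"]], tolerance = 1e-8)
  # at the default k the outlier is down-weighted
  m <- fit_potency_model(d, c0, pod, family = "huber")
  expect_lt(m$weights[3], 1)
  expect_true(all(m$weights > 0 & m$weights <= 1))
  r <- abs(m$residuals)
  expect_true(all((m$weights == 1) == (r <= m$k * m$scale + 1e-12)))
})

test_that("the Huber fit minimises the Huber objective at its converged scale", {
  set.seed(16)
  z <- c(rnorm(12, 2.3, 0.3), 6)  # location problem with one outlier
  d <- data.frame(c0 = rep(1, 13), pod = 10^z)
  m <- fit_potency_model(d, c0, pod, family = "huber")
  b_hat <- m$coefficients[["intercept"]]
  expect_lt(b_hat, mean(z))  # the high outlier is down-weighted
  s <- m$scale; k <- m$k
  rho <- function(u) ifelse(abs(u) <= k, u^2 / 2, k * abs(u) - k^2 / 2)
  obj <- function(b) sum(rho((z - b) / s))
  b_opt <- optimize(obj, c(min(z), max(z)), tol = 1e-10)$minimum
  expect_equal(b_hat, b_opt, tolerance = 1e-6)
})

test_that("the Huber IRLS agrees with the standard robust-regression implementation", {
  skip_if_not_installed("MASS")
  tr <- training_table()
  m <- fit_potency_model(tr, cdv0, cpv, family = "huber")
  r <- MASS::rlm(I(log10(cpv) - log10(cdv0)) ~ 1, data = tr,
                 k = 1.345, maxit = 100)
  expect_equal(m$coefficients[["intercept"]], unname(coef(r)),
               tolerance = 1e-4)
  set.seed(77)
  d <- data.frame(c0 = 10^runif(20, -1, 2))
  d$pod <- 10^(1.5 + 0.9 * log10(d$c0) + rt(20, df = 3) * 0.3)
  ms <- fit_potency_model(d, c0, pod, family = "huber", with_slope = TRUE)
  rs <- MASS::rlm(log10(pod) ~ log10(c0), data = d, k = 1.345, maxit = 100)
  expect_equal(unname(ms$coefficients), unname(coef(rs)), tolerance = 1e-3)
})

test_that("reference-dataset robust intercepts match the published coefficients", {
  tr <- training_table()
  mm <- fit_potency_model(tr, cdv0, cpv, family = "huber", basis = "mass")
  mM <- fit_potency_model(tr, cdv0_molar, cpv_molar, family = "huber",
                          basis = "molar")
  expect_equal(mm$coefficients[["intercept"]], 2.48, tolerance = 0.005)
  expect_equal(mM$coefficients[["intercept"]], -0.521, tolerance = 0.005)
  # the practical multiplier constants
  expect_equal(10^mm$coefficients[["intercept"]], 304, tolerance = 0.01)
  expect_equal(10^mM$coefficients[["intercept"]], 0.301, tolerance = 0.01)
  # asymptotic intercept intervals
  expect_equal(mm$intercept_ci, c(2.32, 2.65), tolerance = 0.05)
  expect_equal(mM$intercept_ci, c(-0.689, -0.353), tolerance = 0.05)
})

test_that("AIC prefers the intercept-only model and follows the Gaussian profile formula", {
  tr <- training_table()
  m0 <- fit_potency_model(tr, cdv0, cpv, family = "ols")
  m1 <- fit_potency_model(tr, cdv0, cpv, family = "ols", with_slope = TRUE)
  expect_lt(AIC(m0), AIC(m1))
  h0 <- fit_potency_model(tr, cdv0, cpv, family = "huber")
  h1 <- fit_potency_model(tr, cdv0, cpv, family = "huber", with_slope = TRUE)
  expect_lt(AIC(h0), AIC(h1))
  # manual formula: n log(RSS/n) + 2(p + 1) + n(log(2 pi) + 1)
  n <- m0$n; rss <- sum(m0$residuals^2)
  expect_equal(AIC(m0), n * log(rss / n) + 2 * 2 + n * (log(2 * pi) + 1),
               tolerance = 1e-9)
  # invariant to row order
  m0b <- fit_potency_model(tr[sample(nrow(tr)), ], cdv0, cpv, family = "ols")
  expect_equal(AIC(m0b), AIC(m0), tolerance = 1e-9)
})

test_that("predictions are fold-change equivariant and match the published constants", {
  tr <- training_table()
  mm <- fit_potency_model(tr, cdv0, cpv, family = "huber", basis = "mass")
  mM <- fit_potency_model(tr, cdv0_molar, cpv_molar, family = "huber",
                          basis = "molar")
  expect_equal(predict(mm, 1), 304, tolerance = 0.01)
  expect_equal(predict(mM, 1), 0.301, tolerance = 0.01)
  x <- c(0.2, 1, 7)
  expect_equal(predict(mm, 2 * x), 2 * predict(mm, x), tolerance = 1e-12)
  expect_error(predict(mm, -1), "positive")
})

test_that("the intercept-only fit recovers a known offset within 3 standard errors", {
  hits <- 0L
  for (seed in 1:10) {
    sim <- simulate_references(n_chemicals = 25, seed = seed)
    cs <- build_composite_scale(sim)
    tr <- tibble::tibble(cdv0 = sim$cdv0, cpv = cs$chemicals$cpv)
    m <- fit_potency_model(tr, cdv0, cpv, family = "huber")
    se <- diff(m$intercept_ci) / (2 * qnorm(0.975))
    if (abs(m$coefficients[["intercept"]] - 2.5) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("degenerate and warning paths behave as documented", {
  d <- data.frame(c0 = rep(2, 5), pod = c(10, 20, 30, 40, 50))
  expect_error(fit_potency_model(d, c0, pod, with_slope = TRUE), "Degenerate")
  m <- fit_potency_model(d, c0, pod)  # intercept-only is fine
  expect_equal(m$coefficients[["slope"]], 1)
  set.seed(2)
  dd <- data.frame(c0 = 10^runif(30), pod = 10^rnorm(30, 2, 1))
  expect_warning(fit_potency_model(dd, c0, pod, family = "huber",
                                   max_iter = 1), "converge")
})
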