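# Independent oracles used across the test files. Each is a deliberately
# plain, loop-based implementation so it cannot share a defect with the
# vectorised package code.

# Offset-corrected median of pairwise slopes, by explicit enumeration.
# Convention: pairs tied in x or y contribute to the offset K together with
# the slopes below -1; slopes of exactly -1 are discarded; odd N takes the
# single order statistic (N+1)/2 + K, even N averages the upper median pair.
oracle_pb_slope <- function(x, y) {
  S <- c(); K <- 0L
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) next
      if (dx == 0 || dy == 0) { K <- K + 1L; if (dy == 0) S <- c(S, 0) ; next }
      s <- dy / dx
      if (s == -1) next
      if (s < -1) K <- K + 1L
      S <- c(S, s)
    }
  }
  S <- sort(S)
  N <- length(S)
  if (N %% 2 == 1) {
    S[min(max((N + 1) / 2 + K, 1), N)]
  } else {
    i <- min(max(N / 2 + 1 + K, 1), N - 1)
    (S[i] + S[i + 1]) / 2
  }
}

# Plain-formula Pearson correlation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Spearman = Pearson on ranks.
oracle_spearman <- function(x, y) oracle_pearson(rank(x), rank(y))

# Two-sided exact Wilcoxon signed-rank p-value by full enumeration of the
# 2^n sign assignments (no ties assumed).
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Zero crossing of the piecewise-linear mean-DV profile located by a dense
# grid scan plus uniroot refinement, in linear or log10 concentration space.
oracle_cdv0 <- function(conc, dv, space = "linear") {
  tx <- if (space == "log") log10(conc) else conc
  f <- stats::approxfun(tx, dv)
  cross <- which(dv[-length(dv)] < 0 & dv[-1] >= 0)[1]
  root <- stats::uniroot(f, c(tx[cross], tx[cross + 1]), tol = 1e-12)$root
  if (space == "log") 10^root else root
}

# The 25 printed composite potency values (mass basis, ug/cm2), in the row
# order of the bundled dataset restricted to complete chemicals.
printed_cpv <- c(
  "2,4-Dinitrochlorobenzene" = 9.80, "Cinnamic aldehyde" = 378,
  "Citral" = 1440, "Diethyl maleate" = 921, "Dimethyl fumarate" = 82.8,
  "Methylisothiazolinone" = 63.4, "Chlorpromazine" = 200,
  "alpha-Isomethylionone" = 21400, "Isoeugenol" = 275,
  "p-Mentha-1,8-dien-7-al" = 835, "Phenylacetaldehyde" = 654,
  "Carvone" = 2980, "7-Hydroxycitronellal" = 5260,
  "5-Methyl-2,3-hexanedione" = 4830, "Eugenol" = 4270,
  "Ethyl acrylate" = 3630, "Cinnamic alcohol" = 4200, "Farnesol" = 1850,
  "Geraniol" = 7220, "Imidazolidinyl urea" = 3490,
  "3-Propylidenephthalide" = 928, "Pentachlorophenol" = 3310,
  "(R)-(+)-Limonene" = 12000, "Benzyl salicylate" = 3790,
  "Linalool" = 12100
)

# Random valid dose-response curve with a single upward crossing.
random_crossing_curve <- function(n_conc = 6) {
  conc <- sort(stats::runif(1, 0.1, 2) * 2^(0:(n_conc - 1)))
  cross_at <- sample(2:(n_conc - 1), 1)
  dv <- c(sort(stats::runif(cross_at, -2, -0.05)),
          sort(stats::runif(n_conc - cross_at, 0.05, 2)))
  data.frame(concentration = conc, dv = dv)
}
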