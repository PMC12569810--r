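# independent profiled-ML oracle for the compound-symmetry GLS: profile
# beta and sigma2 out of the Gaussian likelihood on a grid-free optimiser
gls_cs_oracle <- function(y, X, cluster) {
  cl <- factor(cluster)
  nll <- function(par) {
    rho <- plogis(par)        # (0, 1)
    n <- length(y)
    # GLS for fixed rho: V_i = (1-rho) I + rho J within each cluster
    Wx <- matrix(0, ncol(X), ncol(X)); Wy <- numeric(ncol(X))
    quad <- 0; logdet <- 0
    # first pass with beta = 0 impossible: solve beta from weighted normal eqs
    for (id in levels(cl)) {
      i <- which(cl == id); m <- length(i)
      Vi <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
      Vinv <- solve(Vi)
      Wx <- Wx + t(X[i, , drop = FALSE]) %*% Vinv %*% X[i, , drop = FALSE]
      Wy <- Wy + t(X[i, , drop = FALSE]) %*% Vinv %*% y[i]
      logdet <- logdet + determinant(Vi)$modulus
    }
    beta <- solve(Wx, Wy)
    for (id in levels(cl)) {
      i <- which(cl == id); m <- length(i)
      Vi <- (1 - rho) * diag(m) + rho * matrix(1, m, m)
      r <- y[i] - X[i, , drop = FALSE] %*% beta
      quad <- quad + t(r) %*% solve(Vi, r)
    }
    n <- length(y)
    sigma2 <- as.numeric(quad) / n
    0.5 * (n * log(sigma2) + as.numeric(logdet) + n)
  }
  opt <- optimize(nll, c(-8, 8))
  rho <- plogis(opt$minimum)
  # recompute beta at the optimum
  Wx <- matrix(0, ncol(X), ncol(X)); Wy <- numeric(ncol(X))
  for (id in levels(cl)) {
    i <- which(cl == id); m <- length(i)
    Vinv <- solve((1 - rho) * diag(m) + rho * matrix(1, m, m))
    Wx <- Wx + t(X[i, , drop = FALSE]) %*% Vinv %*% X[i, , drop = FALSE]
    Wy <- Wy + t(X[i, , drop = FALSE]) %*% Vinv %*% y[i]
  }
  list(beta = as.numeric(solve(Wx, Wy)), rho = rho)
}

test_that("compound-symmetry GLS matches the profiled-ML oracle", {
  tab <- synth_brightness_table(brightness_table_config(
    n_animals_per_group = 6, dose_levels = c(0, 1, 2),
    site_offsets = c(60, 50, 40, 0), seed = 41))
  g <- fit_gls_cs(tab)
  X <- model.matrix(~ dose + site, tab)
  orc <- gls_cs_oracle(tab$brightness, X, tab$animal)
  expect_equal(unname(g$coefficients$estimate), orc$beta, tolerance = 1e-4)
  expect_equal(g$rho_hat, unname(orc$rho), tolerance = 1e-3)
})

test_that("GLS reduces to OLS under independence", {
  tab <- synth_brightness_table(brightness_table_config(
    n_animals_per_group = 40, intra_animal_correlation = 0,
    site_offsets = c(30, 20, 10, 0), seed = 42))
  g <- fit_gls_cs(tab)
  ols <- coef(lm(brightness ~ dose + site, tab))
  expect_equal(unname(g$coefficients$estimate), unname(ols),
               tolerance = 1e-2)
  expect_lt(abs(g$rho_hat), 0.08)
  # degenerate designs are rejected with explicit messages
  expect_error(fit_gls_cs(tab[tab$animal == "a001", ]), "2 clusters")
  one_per <- tab[!duplicated(tab$animal), ]
  one_per$site <- NULL
  expect_error(fit_gls_cs(one_per, site = NULL), "singleton")
  expect_error(fit_gls_cs(tab[, -5]), "missing column")
})

test_that("GLS covers the generating dose slope", {
  covered <- logical(30); est <- numeric(30)
  for (r in 1:30) {
    tab <- synth_brightness_table(brightness_table_config(
      n_animals_per_group = 25, dose_slope = -61, seed = 500 + r))
    g <- fit_gls_cs(tab)
    est[r] <- g$coefficients["dose", "estimate"]
    covered[r] <- g$coefficients["dose", "lower"] <= -61 &&
      -61 <= g$coefficients["dose", "upper"]
  }
  expect_gte(mean(covered), 0.8)
  expect_equal(mean(est), -61, tolerance = 0.05)
})

test_that("ANOVA with Tukey-Kramer recovers group differences", {
  # moments chosen to mimic an organ-width comparison: three dose groups
  # with a ~29 um control-vs-high difference at unequal n
  set.seed(43)
  vals <- c(rnorm(30, 160, 12), rnorm(19, 148, 12), rnorm(22, 131, 12))
  grp <- rep(c("control", "low", "high"), c(30, 19, 22))
  a <- anova_tukey(vals, grp)
  expect_lt(a$p, 1e-4)
  row <- a$pairwise[a$pairwise$comparison == "high-control", ]
  expect_lt(row$p_adj, 0.01)
  expect_true(row$lower <= -29 && -29 <= row$upper)
  # two groups: F equals t^2
  x2 <- vals[grp != "low"]; g2 <- grp[grp != "low"]
  a2 <- anova_tukey(x2, g2)
  tt <- t.test(x2 ~ g2, var.equal = TRUE)
  expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a2$p, tt$p.value, tolerance = 1e-9)
  # label relabelling leaves the F statistic unchanged
  a3 <- anova_tukey(vals, paste0("zz_", grp))
  expect_equal(a3$F, a$F)
  # degenerate: zero within-group variance
  expect_warning(d <- anova_tukey(rep(c(1, 2), each = 3),
                                  rep(c("a", "b"), each = 3)),
                 "zero within-group")
  expect_true(d$degenerate)
})

test_that("rank-sum matches hand computation and wilcox.test", {
  x <- c(5, 7, 9, 11, 13); y <- c(1, 2, 3, 4, 6, 8)
  rt <- rank_tests(x, y)
  # hand ranks of x in the combined sample
  expect_equal(rt$ranksum, sum(rank(c(x, y))[1:5]))
  wt <- wilcox.test(x, y, correct = FALSE, exact = FALSE)
  # Matlab-style ranksum = W_wilcox + n1(n1+1)/2
  expect_equal(rt$ranksum, unname(wt$statistic) + 5 * 6 / 2)
  expect_equal(rt$p, wt$p.value, tolerance = 1e-9)
  # identical samples: Z = 0 under tie correction
  expect_warning(rt0 <- rank_tests(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(rt0$Z, 0)
  # invariance under strictly monotone transforms
  rt2 <- rank_tests(exp(x), exp(y))
  expect_equal(rt2$Z, rt$Z)
  # paper-shaped comparison reports both fields with sensible magnitude
  set.seed(44)
  a <- rnorm(26, 13, 4); b <- rnorm(32, 8, 4)
  rp <- rank_tests(a, b)
  expect_true(is.finite(rp$Z) && is.finite(rp$ranksum))
  expect_lt(rp$p, 0.05)
})

test_that("Kruskal-Wallis matches brute-force ranks on a small table", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  kt <- rank_tests(x, groups = g)
  # brute force: H = 12/(N(N+1)) sum n_i (rbar_i - rbar)^2, tie-corrected
  r <- rank(x); N <- length(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * (mean(v) - (N + 1) / 2)^2))
  ties <- table(r)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  expect_equal(kt$statistic, H, tolerance = 1e-9)
  expect_equal(kt$df, 2)
  expect_error(rank_tests(x[1:5], groups = g[1:5]), "3 observations")
})

test_that("threshold regression recovers exact and calibrated fits", {
  # noiseless linear data: exact recovery
  d <- data.frame(age = seq(40, 90, length.out = 30),
                  gap = rep(c(0, 5, 12, 20, 31, 44), 5))
  d$threshold <- 10 + 0.5 * d$age + 0.4 * d$gap
  # noiseless data: lm warns about the (intentionally) perfect fit
  f <- suppressWarnings(fit_threshold_regression(d))
  expect_equal(f$r_squared, 1, tolerance = 1e-9)
  expect_equal(f$coefficients["age", "estimate"], 0.5, tolerance = 1e-9)
  expect_equal(f$coefficients["gap", "estimate"], 0.4, tolerance = 1e-9)
  # added-variable slope equals the fitted coefficient
  av <- f$added_variable$gap
  expect_equal(unname(coef(lm(y_partial ~ x_partial, av))[2]), 0.4,
               tolerance = 1e-6)

  # cohort calibrated to a weak model fit (r^2 ~ 0.18 at n = 105)
  set.seed(45)
  r2 <- replicate(100, {
    n <- 105
    age <- runif(n, 55, 95)
    gap <- pmax(0, rnorm(n, 18, 22))
    signal <- 0.45 * age + 0.2 * gap
    noise_sd <- sd(signal) * sqrt(1 / 0.18 - 1)
    dd <- data.frame(age = age, gap = gap,
                     threshold = 20 + signal + rnorm(n, 0, noise_sd))
    fit_threshold_regression(dd)$r_squared
  })
  expect_equal(mean(r2), 0.18, tolerance = 0.05 / 0.18)

  # permutation null: model p roughly uniform
  set.seed(46)
  pv <- replicate(200, {
    dd <- data.frame(age = runif(40, 50, 90), gap = runif(40, 0, 40),
                     threshold = rnorm(40))
    fit_threshold_regression(dd)$model_p
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif")$p.value), 0.01)
  expect_error(fit_threshold_regression(d[1:3, ]), "too few|missing")
})
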