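#' Compound-symmetry GLS for clustered brightness data
#'
#' Fits `response ~ dose + site` by Gaussian generalised least squares with
#' a compound-symmetric correlation structure within animal (equal
#' correlation between any two sites of the same preparation, independence
#' across preparations), estimated by maximum likelihood via
#' [nlme::gls()]. Wald 95% confidence intervals are reported per
#' coefficient. With the correlation at zero the estimates coincide with
#' ordinary least squares.
#'
#' @param table data.frame with the response, predictors and cluster column
#' @param response name of the response column (default `"brightness"`)
#' @param dose name of the numeric dose predictor (default `"dose"`)
#' @param site name of the categorical site predictor; `NULL` to omit
#' @param cluster name of the animal/preparation id column
#' @param method `"ML"` (default) or `"REML"`
#' @return a `gls_cs_result`: `coefficients` (data.frame with estimate, SE,
#'   lower/upper 95% CI, z, p), `rho_hat`, `sigma_hat`, `loglik`, `n_obs`,
#'   `n_clusters`, and the underlying `nlme` fit as `fit`
#' @export
#' @examples
#' tab <- synth_brightness_table(brightness_table_config(seed = 5))
#' fit_gls_cs(tab)$coefficients["dose", ]
fit_gls_cs <- function(table, response = "brightness", dose = "dose",
                       site = "site", cluster = "animal",
                       method = c("ML", "REML")) {
  method <- match.arg(method)
  table <- as.data.frame(table)
  need <- c(response, dose, site, cluster)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  cl <- table[[cluster]]
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  if (all(table(cl) == 1))
    stop("all clusters are singletons: rho unidentifiable")
  rhs <- paste(c(dose, if (!is.null(site)) site), collapse = " + ")
  fml <- stats::as.formula(paste(response, "~", rhs))
  X <- stats::model.matrix(fml, table)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  table$.cluster <- factor(cl)
  fit <- nlme::gls(fml, data = table,
                   correlation = nlme::corCompSymm(form = ~ 1 | .cluster),
                   method = method)
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- est / se
  co <- data.frame(estimate = est, se = se,
                   lower = est - qnorm(0.975) * se,
                   upper = est + qnorm(0.975) * se,
                   z = z, p = 2 * pnorm(-abs(z)))
  rho <- coef(fit$modelStruct$corStruct, unconstrained = FALSE)
  structure(list(coefficients = co, rho_hat = as.numeric(rho),
                 sigma_hat = fit$sigma, loglik = as.numeric(fit$logLik),
                 n_obs = nrow(table),
                 n_clusters = length(unique(cl)),
                 method = method, fit = fit),
            class = "gls_cs_result")
}

#' @export
print.gls_cs_result <- function(x, ...) {
  cat(sprintf("Compound-symmetry GLS (%s): %d obs in %d clusters, rho = %.3f\n",
              x$method, x$n_obs, x$n_clusters, x$rho_hat))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' One-way ANOVA with Tukey-Kramer post-hoc comparisons
#'
#' One-way analysis of variance across groups followed by all pairwise
#' mean differences with studentized-range (Tukey-Kramer) intervals, valid
#' for unequal group sizes.
#'
#' @param values numeric response
#' @param groups group labels (coerced to factor)
#' @param conf_level familywise confidence level (default 0.95)
#' @return list `F`, `df` (c(between, within)), `p`, `group_means`,
#'   `pairwise` (data.frame: comparison, difference, lower, upper, p_adj),
#'   `degenerate` flag (zero within-group variance everywhere)
#' @export
#' @examples
#' anova_tukey(c(1, 2, 3, 6, 7, 8), rep(c("a", "b"), each = 3))$p
anova_tukey <- function(values, groups, conf_level = 0.95) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  within_var <- tapply(values, groups, var)
  degenerate <- all(within_var == 0)
  if (degenerate) {
    warning("zero within-group variance everywhere; F undefined")
    return(list(F = NA_real_, df = c(nlevels(groups) - 1,
                                     length(values) - nlevels(groups)),
                p = NA_real_,
                group_means = tapply(values, groups, mean),
                pairwise = NULL, degenerate = TRUE))
  }
  fit <- aov(values ~ groups)
  at <- anova(fit)
  tk <- TukeyHSD(fit, conf.level = conf_level)$groups
  pw <- data.frame(comparison = rownames(tk),
                   difference = tk[, "diff"], lower = tk[, "lwr"],
                   upper = tk[, "upr"], p_adj = tk[, "p adj"],
                   row.names = NULL, stringsAsFactors = FALSE)
  list(F = at[1, "F value"], df = at$Df, p = at[1, "Pr(>F)"],
       group_means = tapply(values, groups, mean),
       pairwise = pw, degenerate = FALSE)
}

#' Rank-based tests (rank-sum and Kruskal-Wallis)
#'
#' Two samples give the Wilcoxon-Mann-Whitney rank-sum test reported in
#' the fields customary for cochlear physiology (the rank sum of the first
#' sample and the tie-corrected normal-approximation Z), more than two
#' samples give the Kruskal-Wallis chi-square test.
#'
#' @param x numeric values (first sample, or all values when `groups`
#'   given)
#' @param y second sample (two-sample case)
#' @param groups group labels (k-sample case; overrides `y`)
#' @return for two samples: list `method`, `ranksum`, `Z`, `p`; for k
#'   samples: list `method`, `statistic`, `df`, `p`
#' @export
#' @examples
#' rank_tests(c(5, 7, 9, 11), c(1, 2, 3, 4))$Z
rank_tests <- function(x, y = NULL, groups = NULL) {
  if (!is.null(groups)) {
    groups <- factor(groups)
    if (any(table(groups) < 3)) stop("need >= 3 observations per group")
    kt <- kruskal.test(x, groups)
    return(list(method = "kruskal-wallis",
                statistic = unname(kt$statistic),
                df = unname(kt$parameter), p = kt$p.value))
  }
  if (is.null(y)) stop("provide y or groups")
  if (length(x) < 3 || length(y) < 3)
    stop("need >= 3 observations per sample")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  if (length(unique(c(x, y))) == 1) {
    warning("all observations tied; Z undefined, reported as 0")
    return(list(method = "ranksum", ranksum = sum(r[seq_len(n1)]),
                Z = 0, p = 1))
  }
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  Z <- (W - mu) / sqrt(v)
  list(method = "ranksum", ranksum = W, Z = Z,
       p = 2 * pnorm(-abs(Z)))
}

#' Ordinary least-squares regression of hearing threshold
#'
#' The human-cohort model: hearing threshold at 250 Hz regressed on age
#' and the gap between the organ of Corti and the tectorial membrane by
#' OLS, with the overall F-test, r-squared and added-variable data for
#' partial-effect plots. Complete cases only; severe collinearity is
#' flagged via the design condition number.
#'
#' @param table data.frame containing the variables
#' @param response response column (default `"threshold"`)
#' @param predictors predictor columns (default `c("age", "gap")`)
#' @param condition_limit condition-number bound above which a collinearity
#'   warning is raised
#' @return a `threshold_regression`: `coefficients` (estimate, se, t, p),
#'   `r_squared`, `model_p`, `df_residual`, `added_variable` (list of
#'   data.frames), `condition_number`, `n`, plus the `lm` fit
#' @export
#' @examples
#' d <- data.frame(age = 60:79, gap = rep(c(0, 20), 10))
#' d$threshold <- 20 + 0.5 * d$age + 0.3 * d$gap
#' fit_threshold_regression(d)$r_squared
fit_threshold_regression <- function(table, response = "threshold",
                                     predictors = c("age", "gap"),
                                     condition_limit = 1e6) {
  table <- as.data.frame(table)
  need <- c(response, predictors)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- table[complete.cases(table[, need]), need, drop = FALSE]
  if (nrow(d) <= length(predictors) + 1)
    stop("too few complete cases for the model")
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit <- lm(fml, data = d)
  sm <- summary(fit)
  X <- scale(stats::model.matrix(fit)[, -1, drop = FALSE])
  kappa_n <- if (ncol(X) > 1) kappa(crossprod(X) / (nrow(X) - 1)) else 1
  if (kappa_n > condition_limit)
    warning("severe collinearity: condition number ", format(kappa_n))
  fstat <- sm$fstatistic
  model_p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  av <- lapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    if (length(others)) {
      ry <- stats::resid(lm(stats::reformulate(others, response), data = d))
      rx <- stats::resid(lm(stats::reformulate(others, p), data = d))
    } else {
      ry <- d[[response]] - mean(d[[response]])
      rx <- d[[p]] - mean(d[[p]])
    }
    data.frame(x_partial = rx, y_partial = ry)
  })
  names(av) <- predictors
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "se", "t", "p")
  structure(list(coefficients = co, r_squared = sm$r.squared,
                 model_p = model_p, df_residual = fit$df.residual,
                 added_variable = av, condition_number = kappa_n,
                 n = nrow(d), fit = fit),
            class = "threshold_regression")
}

#' @export
print.threshold_regression <- function(x, ...) {
  cat(sprintf("Threshold regression: n = %d, r^2 = %.3f, model p = %.3g (%d error df)\n",
              x$n, x$r_squared, x$model_p, x$df_residual))
  print(round(x$coefficients, 4))
  invisible(x)
}
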