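#' Configuration for a synthetic molecular-brightness table
#'
#' Generates grouped brightness data with the structure of a multi-site
#' FCS study: each animal is recorded at several sites, observations from
#' one animal share a common random effect, and the marginal mean is
#' `intercept + dose_slope * dose + site_offset`. The implied covariance is
#' compound-symmetric: correlation `rho` between any two sites of one
#' animal, zero across animals, marginal SD `residual_sd`.
#'
#' @param n_animals_per_group animals per dose group
#' @param dose_levels numeric dose per group (one group per element);
#'   default 0/1/2 for control, low and high dose
#' @param sites site labels recorded per animal
#' @param intercept counts/s/molecule at dose 0, reference site
#' @param dose_slope counts/s/molecule per dose unit
#' @param site_offsets named or positional offsets per site
#' @param intra_animal_correlation rho in [0, 1)
#' @param residual_sd marginal SD of one observation
#' @param seed integer RNG seed
#' @return object of class `brightness_table_config`
#' @export
brightness_table_config <- function(n_animals_per_group = 25,
                                    dose_levels = c(0, 1, 2),
                                    sites = c("TM1", "TM2", "TM3", "EndoL"),
                                    intercept = 400,
                                    dose_slope = -61,
                                    site_offsets = rep(0, length(sites)),
                                    intra_animal_correlation = 0.5,
                                    residual_sd = 40, seed = 1L) {
  rho <- intra_animal_correlation
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  m <- length(sites)
  # compound-symmetric covariance must be positive definite
  if (1 + (m - 1) * rho <= 0 || 1 - rho <= 0)
    stop("implied covariance not positive definite")
  if (length(site_offsets) != m) stop("one offset per site required")
  structure(list(n_animals_per_group = as.integer(n_animals_per_group),
                 dose_levels = dose_levels, sites = sites,
                 intercept = intercept, dose_slope = dose_slope,
                 site_offsets = site_offsets,
                 intra_animal_correlation = rho,
                 residual_sd = residual_sd, seed = as.integer(seed)),
            class = "brightness_table_config")
}

#' Simulate a tidy molecular-brightness table
#'
#' Draws the table described by a [brightness_table_config()]: within-animal
#' compound symmetry is realised as a shared animal effect with variance
#' `rho * sd^2` plus site noise with variance `(1 - rho) * sd^2`.
#'
#' @param config a [brightness_table_config()]
#' @return data.frame with columns `animal`, `group`, `dose`, `site`,
#'   `brightness`; the generating parameters are attached as attribute
#'   `truth`
#' @export
#' @examples
#' head(synth_brightness_table(brightness_table_config(seed = 2)))
synth_brightness_table <- function(config) {
  stopifnot(inherits(config, "brightness_table_config"))
  set.seed(config$seed)
  n_g <- length(config$dose_levels)
  n_a <- config$n_animals_per_group
  m <- length(config$sites)
  rho <- config$intra_animal_correlation
  sdv <- config$residual_sd
  rows <- vector("list", n_g)
  aid <- 0L
  for (g in seq_len(n_g)) {
    dose <- config$dose_levels[g]
    a_eff <- rnorm(n_a, sd = sdv * sqrt(rho))
    blocks <- vector("list", n_a)
    for (a in seq_len(n_a)) {
      aid <- aid + 1L
      mu <- config$intercept + config$dose_slope * dose + config$site_offsets
      blocks[[a]] <- data.frame(
        animal = sprintf("a%03d", aid),
        group = paste0("g", g), dose = dose, site = config$sites,
        brightness = mu + a_eff[a] + rnorm(m, sd = sdv * sqrt(1 - rho)),
        stringsAsFactors = FALSE)
    }
    rows[[g]] <- do.call(rbind, blocks)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- config[c("intercept", "dose_slope", "site_offsets",
                                 "intra_animal_correlation", "residual_sd")]
  out
}
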