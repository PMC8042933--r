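## Simulation-based power and type-I error for detecting fitness differences
## between female mating statuses at configurable effect sizes and sample
## sizes.  The study's realized imbalance (many monogamous, few primary and
## secondary females) is the reference scenario.

#' Define a power-simulation scenario
#'
#' @param n_monogamous,n_primary,n_secondary Status group sizes.
#' @param primary,secondary Log-scale status contrasts (vs monogamous) used
#'   to generate counts.
#' @param date_slope Log-scale slope of standardized breeding date.
#' @param family Count kernel (`"cmp"`, `"nbinom"` or `"poisson"`).
#' @param dispersion CMP `nu` or NB `size`.
#' @param zi Zero-inflation probability.
#' @param year_sd SD of the year intercept (log scale).
#' @param n_years Number of seasons the records span.
#' @param intercept Log-scale monogamous mean.
#' @param alpha Nominal level of the Wald tests.
#' @param reps Number of simulation replicates.
#' @param seed Scenario seed.
#' @param id Scenario label.
#' @return A `power_scenario` list.
#' @export
power_scenario <- function(n_monogamous = 2358L, n_primary = 105L,
                           n_secondary = 105L, primary = 0.22,
                           secondary = -0.29, date_slope = -0.29,
                           family = "cmp", dispersion = 0.85, zi = 0.25,
                           year_sd = 0.15, n_years = 19L,
                           intercept = log(0.55), alpha = 0.05, reps = 200L,
                           seed = NULL, id = NULL) {
  if (min(n_monogamous, n_primary, n_secondary) <= 0L)
    stop_bad_arg("all status group sizes must be positive")
  if (alpha <= 0 || alpha >= 1) stop_bad_arg("alpha must be in (0, 1)")
  if (reps < 1L) stop_bad_arg("reps must be >= 1")
  structure(list(n_monogamous = n_monogamous, n_primary = n_primary,
                 n_secondary = n_secondary, primary = primary,
                 secondary = secondary, date_slope = date_slope,
                 family = family, dispersion = dispersion, zi = zi,
                 year_sd = year_sd, n_years = n_years, intercept = intercept,
                 alpha = alpha, reps = as.integer(reps), seed = seed,
                 id = id %||% "scenario"),
            class = "power_scenario")
}

# One scenario's records skeleton (statuses, years, dates); counts are drawn
# per replicate.
scenario_records <- function(sc) {
  n <- sc$n_monogamous + sc$n_primary + sc$n_secondary
  data.frame(female_id = sprintf("F%05d", seq_len(n)),
             year = rep_len(seq_len(sc$n_years), n),
             status = rep(c("monogamous", "primary", "secondary"),
                          c(sc$n_monogamous, sc$n_primary, sc$n_secondary)),
             breeding_date = 0, fledglings = 0L,
             stringsAsFactors = FALSE)
}

#' Estimate power by replicated simulation and refitting
#'
#' For each replicate, fitness counts are generated under the scenario with
#' [simulate_fitness()] and refitted with [fit_zi_count_glmm()]; the power of
#' a contrast is the fraction of replicates whose Wald p-value falls below
#' `alpha`.
#'
#' @param scenario A [power_scenario()].
#' @param seed Overrides the scenario seed.
#' @return A `power_result` data frame with one row per contrast: rejection
#'   rate, its binomial Monte-Carlo SE, replicates used and the
#'   non-convergence count; the result is flagged unreliable when more than
#'   20% of replicates fail.
#' @export
estimate_power <- function(scenario, seed = scenario$seed) {
  sc <- scenario
  cfg <- sim_config()
  cfg$fitness$recruits <- list(family = sc$family, intercept = sc$intercept,
                               primary = sc$primary, secondary = sc$secondary,
                               date = sc$date_slope, zi = sc$zi,
                               dispersion = sc$dispersion, year_sd = sc$year_sd)
  base <- scenario_records(sc)
  seeds <- derive_seeds(seed, 2L * sc$reps)
  hits <- matrix(NA, sc$reps, 2L, dimnames = list(NULL, c("primary", "secondary")))
  nonconv <- 0L
  for (r in seq_len(sc$reps)) {
    rec <- base
    rec$breeding_date <- with_seed(seeds[[r]], stats::rnorm(nrow(base), 145, 8))
    rec <- simulate_fitness(rec, cfg, seed = seeds[[sc$reps + r]])
    fit <- try(fit_zi_count_glmm(rec, "recruits", family = sc$family,
                                 zi = TRUE, random_year = TRUE), silent = TRUE)
    if (inherits(fit, "try-error") || !fit$converged ||
        any(!is.finite(fit$coefficients$p))) {
      nonconv <- nonconv + 1L
      next
    }
    ct <- fit$coefficients
    hits[r, "primary"] <- ct$p[ct$term == "primary_vs_monogamous"] < sc$alpha
    hits[r, "secondary"] <- ct$p[ct$term == "secondary_vs_monogamous"] < sc$alpha
  }
  used <- colSums(!is.na(hits))
  pw <- colMeans(hits, na.rm = TRUE)
  out <- data.frame(id = sc$id, contrast = colnames(hits),
                    effect = c(sc$primary, sc$secondary),
                    n_secondary = sc$n_secondary, reps_used = used,
                    power = pw, mc_se = sqrt(pw * (1 - pw) / pmax(used, 1L)),
                    nonconverged = nonconv,
                    unreliable = nonconv > 0.2 * sc$reps,
                    row.names = NULL)
  class(out) <- c("power_result", class(out))
  out
}

#' Run a grid of power scenarios
#'
#' @param scenarios List of [power_scenario()] objects with distinct ids.
#' @param seed Master seed; each scenario receives an independent derived
#'   seed.
#' @return Row-bound `power_result` table.
#' @export
run_scenario_grid <- function(scenarios, seed = NULL) {
  if (!length(scenarios)) stop_bad_arg("at least one scenario is required")
  ids <- vapply(scenarios, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_bad_arg("duplicate scenario ids")
  seeds <- derive_seeds(seed, length(scenarios))
  out <- do.call(rbind, Map(function(sc, sd) estimate_power(sc, seed = sd),
                            scenarios, seeds))
  rownames(out) <- NULL
  out
}
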