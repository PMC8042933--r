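## Generative configuration for synthetic breeding populations.
##
## The defaults describe a 19-season nest-box population of a migratory,
## hole-nesting passerine in an elongated woodland plot: ~180 boxes at ~77%
## occupancy (~2,630 female-nests over the study), laying onsets in a
## day-120..181 window, social polygyny confined to 1st-2nd order territory
## neighbours at ~4% of female-nests, and a small fraction (~2.2%) of nests
## never observed with a provisioning male ("unassisted").  Effect structure:
## laying dates respond to neighbourhood-relative phenotype; the per-pair
## polygyny probability is logistic in the candidate-pair covariates; fitness
## counts are zero-inflated (Conway-Maxwell-Poisson recruits, negative
## binomial grand-offspring) with mating-status contrasts and a breeding-date
## slope on the log-mean scale.

#' Configuration for the synthetic-population generator
#'
#' Builds a validated generator configuration.  Any field can be overridden;
#' the defaults are the package's reference study conditions and are the ones
#' exercised by the acceptance checks.
#'
#' @param n_seasons Number of breeding seasons.
#' @param n_boxes Number of nest boxes in the plot.
#' @param extent Plot rectangle `c(xmin, xmax, ymin, ymax)` in metres.
#' @param occupancy_rate Probability that a box holds a breeding pair in a
#'   season.
#' @param season_start,season_length Day-of-year window for laying onsets.
#' @param phenotype_means,phenotype_sds Per-sex named vectors of phenotype
#'   means/SDs (tarsus mm, wing mm; males also forehead patch mm^2 and dorsal
#'   blackness %).
#' @param age_geom_p,age_max Age distribution: truncated geometric on
#'   `1..age_max` with success probability `age_geom_p` (~50% yearlings at the
#'   default).
#' @param return_rate Probability that a breeder returns the next season.
#' @param phenology List: `baseline` (mean onset day), `year_sd` (season
#'   effect SD, days), `bird_sd_male`, `bird_sd_female` (repeatable individual
#'   date effects, days), `noise_sd` (nest-level noise, days), and per-sex
#'   coefficient vectors `male`, `female`: days per raw unit of the
#'   neighbourhood-relative trait (mm for tarsus and wing, mm^2 for the
#'   forehead patch, percentage points for blackness); age enters through a
#'   standardized orthogonal quadratic basis as `age1`, `age2` (days per SD).
#' @param polygyny List: `coeffs` (named logit-scale coefficients over the 15
#'   candidate-pair model terms plus `intercept`), `max_order` (largest
#'   neighbour order at which polygyny can occur), `interlay_p`,
#'   `interlay_max` (zero-truncated geometric inter-laying interval between a
#'   male's two females, days), `order_rule` (`"relay"`: a drawn secondary
#'   whose date precedes the primary's is re-laid at primary + interval;
#'   `"swap"`: the male's two females exchange primary/secondary roles),
#'   `unassisted_rate` and `unassisted_from` (which statuses can be relabelled
#'   unassisted).
#' @param fitness Per-response lists (`recruits`, `grand_offspring`) with
#'   `family` (`"cmp"` or `"nbinom"`), log-scale `intercept`, `primary` and
#'   `secondary` contrasts (monogamous is the reference), `date` slope per SD
#'   of breeding date, zero-inflation probability `zi`, `dispersion` (CMP
#'   `nu` or NB `size`) and `year_sd`; plus `clutch_mean` and `fledge_prob`
#'   for clutch/fledgling counts.
#' @param seed Default seed used by [simulate_population()] when none is
#'   given.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_seasons = 19L,
                       n_boxes = 180L,
                       extent = c(0, 4500, 0, 80),
                       occupancy_rate = 0.768,
                       season_start = 120L,
                       season_length = 61L,
                       phenotype_means = list(
                         male = c(tarsus = 19.6, wing = 79.5, forehead = 45, blackness = 55),
                         female = c(tarsus = 19.4, wing = 77.8)),
                       phenotype_sds = list(
                         male = c(tarsus = 0.55, wing = 1.9, forehead = 12, blackness = 22),
                         female = c(tarsus = 0.55, wing = 1.8)),
                       age_geom_p = 0.45,
                       age_max = 6L,
                       return_rate = 0.40,
                       phenology = list(
                         baseline = 142,
                         year_sd = sqrt(1.5),
                         bird_sd_male = 3.09,
                         bird_sd_female = 3.46,
                         noise_sd = 0.93,
                         male = c(tarsus = 1.18, age1 = -1.59, age2 = 1.04,
                                  forehead = -0.05, blackness = -0.01, wing = -0.54),
                         female = c(tarsus = 0.90, age1 = -2.08, age2 = 1.68,
                                    wing = -0.71)),
                       polygyny = list(
                         coeffs = c(intercept = -5.25,
                                    distance = -0.05,
                                    f_asyn = 0.05, f_nneigh = 0.01, f_tarsus = 0.13,
                                    f_age1 = -0.01, f_age2 = -0.15, f_wing = -0.07,
                                    m_asyn = -0.09, m_nneigh = -0.03, m_tarsus = 0.15,
                                    m_age1 = 0.03, m_age2 = -0.28, m_forehead = 0.00,
                                    m_blackness = -0.01, m_wing = 0.08),
                         max_order = 2L,
                         interlay_p = 0.35,
                         interlay_max = 23L,
                         order_rule = "relay",
                         unassisted_rate = 59 / 2627,
                         unassisted_from = "monogamous"),
                       fitness = list(
                         recruits = list(family = "cmp", intercept = log(0.55),
                                         primary = 0.22, secondary = -0.29,
                                         date = -0.29, zi = 0.25,
                                         dispersion = 0.85, year_sd = 0.15),
                         grand_offspring = list(family = "nbinom", intercept = log(1.3),
                                                primary = 0.30, secondary = -0.26,
                                                date = -0.05, zi = 0.20,
                                                dispersion = 0.8, year_sd = 0.15),
                         clutch_mean = 5.8,
                         fledge_prob = 0.72),
                       seed = NULL) {
  cfg <- structure(list(n_seasons = as.integer(n_seasons), n_boxes = as.integer(n_boxes),
                        extent = as.numeric(extent), occupancy_rate = occupancy_rate,
                        season_start = as.integer(season_start),
                        season_length = as.integer(season_length),
                        phenotype_means = phenotype_means, phenotype_sds = phenotype_sds,
                        age_geom_p = age_geom_p, age_max = as.integer(age_max),
                        return_rate = return_rate, phenology = phenology,
                        polygyny = polygyny, fitness = fitness, seed = seed),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_boxes < 2L) stop_bad_arg("n_boxes must be >= 2")
    if (n_seasons < 1L) stop_bad_arg("n_seasons must be >= 1")
    if (length(extent) != 4L || extent[2L] <= extent[1L] || extent[4L] <= extent[3L])
      stop_bad_arg("extent must be c(xmin, xmax, ymin, ymax) with positive area")
    for (p in c(occupancy_rate, polygyny$unassisted_rate,
                fitness$recruits$zi, fitness$grand_offspring$zi))
      if (p < 0 || p > 1) stop_bad_arg("probabilities must lie in [0, 1]")
    for (s in c(unlist(phenotype_sds), phenology$year_sd, phenology$bird_sd_male,
                phenology$bird_sd_female, phenology$noise_sd))
      if (s < 0) stop_bad_arg("standard deviations must be >= 0")
    if (fitness$recruits$dispersion <= 0 || fitness$grand_offspring$dispersion <= 0)
      stop_bad_arg("dispersion parameters must be > 0")
    if (polygyny$max_order < 1L) stop_bad_arg("polygyny max_order must be >= 1")
    if (!polygyny$order_rule %in% c("relay", "swap"))
      stop_bad_arg("order_rule must be 'relay' or 'swap'")
    if (season_length < 1L) stop_bad_arg("season_length must be >= 1")
  })
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic population configuration\n",
      " seasons:", x$n_seasons, " boxes:", x$n_boxes,
      " occupancy:", x$occupancy_rate, "\n",
      " laying window: day", x$season_start, "-", x$season_start + x$season_length, "\n",
      " polygyny max neighbour order:", x$polygyny$max_order,
      " intercept:", x$polygyny$coeffs[["intercept"]], "\n")
  invisible(x)
}
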