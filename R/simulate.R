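## Synthetic multi-season breeding populations with the effect structure the
## downstream analyses assume: linear-Gaussian laying-date phenology on
## neighbourhood-relative phenotype, logistic social polygyny on the
## candidate-pair scale, and zero-inflated count fitness.  Parameter-recovery
## simulation against these generating values is the package's main
## correctness surface.

#' Jittered-grid nest-box coordinates
#'
#' Lays boxes on a regular grid matched to the plot's aspect ratio and
#' jitters each box uniformly within its grid cell, so coordinates are
#' distinct by construction and the spacing resembles a managed nest-box
#' scheme.
#'
#' @param n_boxes Number of boxes (>= 2).
#' @param extent Plot rectangle `c(xmin, xmax, ymin, ymax)` in metres.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `box_id`, `x`, `y`.
#' @export
simulate_nest_grid <- function(n_boxes, extent, seed = NULL) {
  if (n_boxes < 2L) stop_bad_arg("n_boxes must be >= 2")
  w <- extent[2L] - extent[1L]; h <- extent[4L] - extent[3L]
  if (!is.finite(w) || !is.finite(h) || w <= 0 || h <= 0)
    stop_bad_arg("degenerate extent")
  with_seed(seed, {
    nx <- max(1L, round(sqrt(n_boxes * w / h)))
    ny <- ceiling(n_boxes / nx)
    cells <- utils::head(expand.grid(ix = seq_len(nx), iy = seq_len(ny)), n_boxes)
    dx <- w / nx; dy <- h / ny
    data.frame(box_id = sprintf("B%03d", seq_len(n_boxes)),
               x = extent[1L] + (cells$ix - stats::runif(n_boxes, 0.15, 0.85)) * dx,
               y = extent[3L] + (cells$iy - stats::runif(n_boxes, 0.15, 0.85)) * dy)
  })
}

# Truncated geometric ages on 1..age_max (~50% yearlings at p = 0.45).
draw_ages <- function(n, p, age_max) {
  pr <- p * (1 - p)^(0:(age_max - 1L))
  sample.int(age_max, n, replace = TRUE, prob = pr / sum(pr))
}

#' Draw phenotypes for a cohort of birds
#'
#' @param config A [sim_config()].
#' @param n_males,n_females Cohort sizes.
#' @param seed Optional RNG seed.
#' @param id_offset Offset for generated bird-id numbers (used when cohorts
#'   accumulate across seasons).
#' @return Data frame with `bird_id`, `sex`, `age`, `tarsus`, `wing`, and the
#'   male-only ornaments `forehead` (patch area, mm^2) and `blackness`
#'   (dorsal black plumage, %), `NA` for females.
#' @export
simulate_phenotypes <- function(config, n_males, n_females, seed = NULL,
                                id_offset = 0L) {
  mm <- config$phenotype_means$male; ms <- config$phenotype_sds$male
  fm <- config$phenotype_means$female; fs <- config$phenotype_sds$female
  with_seed(seed, {
    males <- if (n_males > 0L)
      data.frame(bird_id = sprintf("M%05d", id_offset + seq_len(n_males)),
                 sex = "male",
                 age = draw_ages(n_males, config$age_geom_p, config$age_max),
                 tarsus = stats::rnorm(n_males, mm[["tarsus"]], ms[["tarsus"]]),
                 wing = stats::rnorm(n_males, mm[["wing"]], ms[["wing"]]),
                 forehead = pmax(stats::rnorm(n_males, mm[["forehead"]], ms[["forehead"]]), 1),
                 blackness = pmin(pmax(stats::rnorm(n_males, mm[["blackness"]], ms[["blackness"]]), 0), 100))
    else NULL
    females <- if (n_females > 0L)
      data.frame(bird_id = sprintf("F%05d", id_offset + seq_len(n_females)),
                 sex = "female",
                 age = draw_ages(n_females, config$age_geom_p, config$age_max),
                 tarsus = stats::rnorm(n_females, fm[["tarsus"]], fs[["tarsus"]]),
                 wing = stats::rnorm(n_females, fm[["wing"]], fs[["wing"]]),
                 forehead = NA_real_, blackness = NA_real_)
    else NULL
    rbind(males, females)
  })
}

# Neighbourhood-relative trait effects on the laying date of each nest,
# using the direct (order-1) neighbourhood.  Morphological coefficients are
# in days per raw unit of the relative trait (mm, mm^2, %); age contributes
# through a standardized orthogonal quadratic basis (days per SD), mirroring
# how the phenology models treat age.
phenology_trait_effect <- function(nests, birds, tess, coeffs, sex) {
  pre <- if (sex == "male") "m_" else "f_"
  nv <- season_nest_values(nests, birds)
  ids <- tess$ids
  nv <- nv[match(ids, nv$nest_id), ]
  M <- (tess$order == 1) * 1
  n1 <- rowSums(M)
  n1[n1 == 0] <- NA
  traits <- c("tarsus", "wing", "age", if (sex == "male") c("forehead", "blackness"))
  rel <- sapply(traits, function(tr) {
    v <- nv[[paste0(pre, tr)]]
    v - (M %*% v) / n1
  })
  colnames(rel) <- traits
  eff <- numeric(length(ids))
  for (tr in setdiff(traits, "age")) {
    v <- rel[, tr] - mean(rel[, tr], na.rm = TRUE)
    eff <- eff + coeffs[[tr]] * v
  }
  if (length(unique(rel[, "age"])) >= 3L) {
    pb <- stats::poly(rel[, "age"], 2)
    z1 <- pb[, 1L] / stats::sd(pb[, 1L]); z2 <- pb[, 2L] / stats::sd(pb[, 2L])
    eff <- eff + coeffs[["age1"]] * z1 + coeffs[["age2"]] * z2
  }
  eff[match(nests$nest_id, ids)]
}

#' Simulate laying dates for one season
#'
#' Laying onset = season baseline + standardized relative-trait effects of
#' both pair members + repeatable individual date effects + nest-level noise,
#' rounded to the day and clamped to the season window.
#'
#' @param nests,birds One season's nest and phenotype tables.
#' @param tess The season's tessellation.
#' @param config A [sim_config()].
#' @param year_effect Season intercept deviation (days).
#' @param bird_effects Named vector of individual date effects (days) keyed by
#'   bird id.
#' @param seed Optional RNG seed.
#' @return Integer laying dates aligned with `nests` rows.
#' @export
simulate_laying_dates <- function(nests, birds, tess, config, year_effect = 0,
                                  bird_effects = NULL, seed = NULL) {
  ph <- config$phenology
  miss <- setdiff(c(nests$male_id, nests$female_id), c(NA, birds$bird_id))
  if (length(miss)) stop_bad_arg("missing phenotype record(s): ",
                                 paste(utils::head(miss), collapse = ", "))
  with_seed(seed, {
    n <- nrow(nests)
    nests$laying_date <- 0
    em <- phenology_trait_effect(nests, birds, tess, ph$male, "male")
    ef <- phenology_trait_effect(nests, birds, tess, ph$female, "female")
    bm <- bird_effects[nests$male_id]; bf <- bird_effects[nests$female_id]
    bm[is.na(bm)] <- 0; bf[is.na(bf)] <- 0
    d <- ph$baseline + year_effect + ifelse(is.na(em), 0, em) +
      ifelse(is.na(ef), 0, ef) + bm + bf + stats::rnorm(n, 0, ph$noise_sd)
    as.integer(pmin(pmax(round(d), config$season_start),
                    config$season_start + config$season_length))
  })
}

# Zero-truncated geometric inter-laying interval (days).
draw_interlay <- function(n, p, max) {
  pmin(1L + stats::rgeom(n, p), max)
}

#' Assign social polygyny across a population
#'
#' Draws polygyny events on the candidate-pair scale: every order-filtered
#' male-female combination receives an independent Bernoulli draw with
#' probability `plogis(X beta)`, where `X` is the standardized 15-term
#' candidate-pair design (the same construction the polygyny model fits) and
#' `beta = config$polygyny$coeffs`.  Conflicts are resolved in random order so
#' that every male gains at most one secondary female and every female is
#' secondary to at most one male; the displaced male of a taken nest leaves
#' the data.  If a drawn secondary's laying date does not follow the
#' primary's, the ordering is restored by the configured `order_rule`
#' (re-laying her clutch at primary + inter-laying interval, or swapping the
#' two females' roles).
#'
#' @param pop A provisional `breeding_population` (all-monogamous statuses).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return The population with statuses, re-laid dates and displaced males
#'   resolved; realized events are recorded in `attr(, "events")`.
#' @export
assign_polygyny <- function(pop, config, seed = NULL) {
  cf <- config$polygyny
  terms <- c("distance", "f_asyn", "f_nneigh", "f_tarsus", "f_age1", "f_age2",
             "f_wing", "m_asyn", "m_nneigh", "m_tarsus", "m_age1", "m_age2",
             "m_forehead", "m_blackness", "m_wing")
  if (!all(c("intercept", terms) %in% names(cf$coeffs)))
    stop_bad_arg("polygyny coefficient vector is incomplete")
  pairs <- build_pair_data(pop, rule = "inclusive", max_order = cf$max_order,
                           prospective_male = TRUE)
  des <- build_polygyny_design(pairs)
  eta <- drop(des$X %*% cf$coeffs[colnames(des$X)]) + cf$coeffs[["intercept"]]
  pr <- des$pairs
  with_seed(seed, {
    hit <- which(stats::runif(nrow(pr)) < stats::plogis(eta))
    hit <- hit[sample.int(length(hit))]           # random processing order
    nests <- pop$nests
    key <- paste(nests$year, nests$nest_id)
    has_secondary <- character(0); taken <- character(0); displaced <- character(0)
    events <- list()
    for (i in hit) {
      yr <- pr$year[i]; m <- pr$male_id[i]; f <- pr$female_id[i]
      fn <- which(key == paste(yr, pr$female_nest[i]))
      mn <- which(key == paste(yr, pr$male_nest[i]))
      m_f <- nests$male_id[fn]                    # the female's current male
      ym <- paste(yr, m); yf <- paste(yr, f); ymf <- paste(yr, m_f)
      if (ym %in% c(has_secondary, displaced)) next
      if (yf %in% taken) next
      if (ymf %in% c(has_secondary, displaced)) next
      has_secondary <- c(has_secondary, ym)
      taken <- c(taken, yf)
      displaced <- c(displaced, ymf)
      nests$male_id[fn] <- m
      d_p <- nests$laying_date[mn]; d_s <- nests$laying_date[fn]
      relaid <- FALSE
      if (d_s <= d_p) {
        if (cf$order_rule == "relay") {
          nests$laying_date[fn] <- min(d_p + draw_interlay(1L, cf$interlay_p, cf$interlay_max),
                                       config$season_start + config$season_length)
          if (nests$laying_date[fn] <= d_p) nests$laying_date[fn] <- d_p + 1L
          relaid <- TRUE
        } else {                                  # swap primary/secondary roles
          tmp <- fn; fn <- mn; mn <- tmp
        }
      }
      nests$female_status[mn] <- "primary"
      nests$female_status[fn] <- "secondary"
      events[[length(events) + 1L]] <-
        data.frame(year = yr, male_id = m, drawn_female = f,
                   displaced_male = m_f, relaid = relaid)
    }
    # displaced males vanish from the season's phenotype table
    if (length(displaced)) {
      drop <- paste(pop$birds$year, pop$birds$bird_id) %in% displaced
      pop$birds <- pop$birds[!drop, ]
    }
    pop$nests <- nests
    attr(pop, "events") <- if (length(events)) do.call(rbind, events) else NULL
    pop
  })
}

#' Simulate fitness counts for female breeding records
#'
#' Draws the direct (recruits) and indirect (grand-offspring) fitness counts
#' from the configured zero-inflated distributions with log-link mean
#' `exp(intercept + status contrast + date slope * standardized breeding date
#' + year effect)`.
#'
#' @param records Data frame with `female_id`, `year`, `status`,
#'   `breeding_date` (and optionally `fledglings`).
#' @param config A [sim_config()]; `config$fitness` holds the generating
#'   coefficients.
#' @param seed Optional RNG seed.
#' @return `records` with `recruits`, `grand_offspring` and a `fledglings`
#'   column consistent with `recruits <= fledglings`.
#' @export
simulate_fitness <- function(records, config, seed = NULL) {
  fx <- config$fitness
  with_seed(seed, {
    n <- nrow(records)
    dsd <- stats::sd(records$breeding_date)
    zdate <- if (is.na(dsd) || dsd == 0) rep(0, n)
             else (records$breeding_date - mean(records$breeding_date)) / dsd
    if (is.null(records$fledglings))
      records$fledglings <- stats::rbinom(n, pmax(1L, stats::rpois(n, fx$clutch_mean)),
                                          fx$fledge_prob)
    yrs <- sort(unique(records$year))
    draw <- function(par) {
      contrast <- c(monogamous = 0, unassisted = 0,
                    primary = par$primary, secondary = par$secondary)
      u <- stats::rnorm(length(yrs), 0, par$year_sd)
      mu <- exp(par$intercept + contrast[records$status] + par$date * zdate +
                  u[match(records$year, yrs)])
      if (par$family == "cmp") rzicmp(n, mu, par$dispersion, par$zi)
      else rzinb(n, mu, par$dispersion, par$zi)
    }
    records$recruits <- draw(fx$recruits)
    records$grand_offspring <- draw(fx$grand_offspring)
    records$fledglings <- pmax(records$fledglings, records$recruits)
    records
  })
}

#' Simulate a complete multi-season breeding population
#'
#' Runs the full generative pipeline: nest-box layout, per-season occupancy
#' and pairing with between-season survival, phenotypes, territory
#' tessellations, phenotype-dependent laying dates, candidate-pair-scale
#' polygyny assignment, unassisted relabelling, and zero-inflated fitness
#' counts.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`); all stages derive
#'   their streams from it.
#' @return An object of class `breeding_population`: data frames `nests`,
#'   `birds` (one row per bird-year), `fitness`, the per-season
#'   `tessellations`, the `config` and the `seed`.
#' @export
simulate_population <- function(config = sim_config(), seed = config$seed) {
  validate_sim_config(config)
  seeds <- derive_seeds(seed %||% stats::runif(1, 1, 2^30), 6L)
  boxes <- simulate_nest_grid(config$n_boxes, config$extent, seeds[[1L]])
  ph <- config$phenology
  nests_all <- list(); birds_all <- list(); tessellations <- list()
  with_seed(seeds[[2L]], {
    year_eff <- stats::rnorm(config$n_seasons, 0, ph$year_sd)
    pool_m <- NULL; pool_f <- NULL     # returning breeders
    id_counter <- 0L
    bird_re <- numeric(0)              # individual date effects, by bird id
    for (y in seq_len(config$n_seasons)) {
      occ <- which(stats::runif(config$n_boxes) < config$occupancy_rate)
      n_n <- length(occ)
      if (n_n < 2L) next
      surv <- function(pool) {
        if (is.null(pool)) return(NULL)
        keep <- stats::runif(nrow(pool)) < config$return_rate
        pool <- pool[keep, , drop = FALSE]
        pool$age <- pool$age + 1L
        pool[pool$age <= config$age_max, , drop = FALSE]
      }
      pool_m <- surv(pool_m); pool_f <- surv(pool_f)
      need_m <- max(0L, n_n - NROW(pool_m)); need_f <- max(0L, n_n - NROW(pool_f))
      fresh <- simulate_phenotypes(config, need_m, need_f, seed = NULL,
                                   id_offset = id_counter)
      id_counter <- id_counter + max(need_m, need_f)
      new_ids <- setdiff(fresh$bird_id, names(bird_re))
      sds <- ifelse(startsWith(new_ids, "M"), ph$bird_sd_male, ph$bird_sd_female)
      bird_re <- c(bird_re, stats::setNames(stats::rnorm(length(new_ids), 0, sds), new_ids))
      males <- rbind(pool_m, if (!is.null(fresh)) fresh[fresh$sex == "male", ])
      females <- rbind(pool_f, if (!is.null(fresh)) fresh[fresh$sex == "female", ])
      males <- males[sample.int(nrow(males), n_n), ]
      females <- females[sample.int(nrow(females), n_n), ]
      pool_m <- males; pool_f <- females          # breeders may return next year
      nests <- data.frame(year = y, nest_id = boxes$box_id[occ],
                          x = boxes$x[occ], y = boxes$y[occ],
                          laying_date = NA_integer_,
                          male_id = males$bird_id, female_id = females$bird_id,
                          female_status = "monogamous",
                          stringsAsFactors = FALSE)
      birds <- rbind(cbind(year = y, males), cbind(year = y, females))
      tess <- build_tessellation(data.frame(id = nests$nest_id, x = nests$x, y = nests$y),
                                 year = y)
      nests$laying_date <- simulate_laying_dates(nests, birds, tess, config,
                                                 year_effect = year_eff[y],
                                                 bird_effects = bird_re)
      nests_all[[y]] <- nests; birds_all[[y]] <- birds
      tessellations[[as.character(y)]] <- tess
    }
  })
  pop <- structure(list(nests = do.call(rbind, nests_all),
                        birds = do.call(rbind, birds_all),
                        tessellations = tessellations,
                        fitness = NULL, config = config, seed = seed),
                   class = "breeding_population")
  pop <- assign_polygyny(pop, config, seed = seeds[[3L]])
  pop <- relabel_unassisted(pop, config, seed = seeds[[4L]])
  # fitness records: one per female-nest
  rec <- pop$nests[, c("female_id", "year", "female_status", "laying_date")]
  names(rec) <- c("female_id", "year", "status", "breeding_date")
  with_seed(seeds[[5L]], {
    n <- nrow(rec)
    clutch <- pmax(1L, stats::rpois(n, config$fitness$clutch_mean))
    pop$nests$clutch <- clutch
    pop$nests$fledglings <- stats::rbinom(n, clutch, config$fitness$fledge_prob)
  })
  rec$fledglings <- pop$nests$fledglings
  rec <- simulate_fitness(rec, config, seed = seeds[[6L]])
  pop$nests$fledglings <- rec$fledglings
  pop$fitness <- rec
  pop
}

# Relabel a configured fraction of nests as unassisted (male never observed);
# their males leave the data.
relabel_unassisted <- function(pop, config, seed = NULL) {
  cf <- config$polygyny
  if (cf$unassisted_rate <= 0) return(pop)
  eligible <- if (identical(cf$unassisted_from, "monogamous")) "monogamous"
              else c("monogamous", "secondary")
  with_seed(seed, {
    idx <- which(pop$nests$female_status %in% eligible)
    n_un <- stats::rbinom(1L, nrow(pop$nests), cf$unassisted_rate)
    idx <- sample(idx, min(n_un, length(idx)))
    if (length(idx)) {
      gone <- paste(pop$nests$year[idx], pop$nests$male_id[idx])
      pop$nests$female_status[idx] <- "unassisted"
      pop$nests$male_id[idx] <- NA_character_
      still <- paste(pop$nests$year, pop$nests$male_id)
      gone <- setdiff(gone, still)
      pop$birds <- pop$birds[!paste(pop$birds$year, pop$birds$bird_id) %in% gone, ]
    }
    pop
  })
}

#' @export
print.breeding_population <- function(x, ...) {
  st <- table(x$nests$female_status)
  cat("Synthetic breeding population\n",
      " seasons:", length(unique(x$nests$year)),
      "  female-nests:", nrow(x$nests), "\n  status counts:",
      paste(names(st), as.integer(st), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a population as plain-text CSVs
#'
#' Writes `nests.csv`, `birds.csv`, `fitness.csv` and a `metadata.yaml`
#' carrying the seed and a hash of the configuration.
#'
#' @param pop A `breeding_population`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nests <- pop$nests[, c("nest_id", "x", "y", "year", "laying_date", "male_id",
                         "female_id", "female_status", "clutch", "fledglings")]
  utils::write.csv(nests, file.path(dir, "nests.csv"), row.names = FALSE)
  utils::write.csv(pop$birds, file.path(dir, "birds.csv"), row.names = FALSE)
  utils::write.csv(pop$fitness, file.path(dir, "fitness.csv"), row.names = FALSE)
  cfgf <- file.path(dir, "config.yaml")
  yaml::write_yaml(pop$config, cfgf)
  yaml::write_yaml(list(seed = pop$seed,
                        config_md5 = unname(tools::md5sum(cfgf)),
                        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                   file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' @rdname write_population
#' @export
read_population <- function(dir) {
  nests <- utils::read.csv(file.path(dir, "nests.csv"), stringsAsFactors = FALSE)
  birds <- utils::read.csv(file.path(dir, "birds.csv"), stringsAsFactors = FALSE)
  fit <- utils::read.csv(file.path(dir, "fitness.csv"), stringsAsFactors = FALSE)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  tess <- lapply(split(nests, nests$year), function(nn)
    build_tessellation(data.frame(id = nn$nest_id, x = nn$x, y = nn$y),
                       year = nn$year[1L]))
  structure(list(nests = nests, birds = birds, tessellations = tess,
                 fitness = fit, config = cfg, seed = NULL),
            class = "breeding_population")
}
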