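# Synthetic-population generator: layout, phenotypes, dates, polygyny,
# fitness, and the structural invariants of generated seasons.

test_that("nest grid: distinct jittered coordinates inside the extent, seeded", {
  g <- simulate_nest_grid(4, c(0, 100, 0, 100), seed = 1)
  expect_equal(nrow(g), 4L)
  expect_gt(min(dist(g[, c("x", "y")])), 0)
  expect_identical(simulate_nest_grid(50, c(0, 500, 0, 500), seed = 7),
                   simulate_nest_grid(50, c(0, 500, 0, 500), seed = 7))
  big <- simulate_nest_grid(100, c(0, 500, 0, 500), seed = 3)
  expect_gt(min(dist(big[, c("x", "y")])), 0)       # brute-force pairwise check
  expect_true(all(big$x >= 0 & big$x <= 500 & big$y >= 0 & big$y <= 500))
  expect_error(simulate_nest_grid(1, c(0, 1, 0, 1)), "n_boxes")
  expect_error(simulate_nest_grid(5, c(0, 0, 0, 1)), "extent")
})

test_that("phenotypes: degenerate SDs collapse to identical birds; empty cohorts ok", {
  cfg <- sim_config()
  cfg$phenotype_sds <- lapply(cfg$phenotype_sds, function(v) v * 0)
  b <- simulate_phenotypes(cfg, 20, 20, seed = 2)
  b$age <- NULL  # ages keep their distribution
  expect_equal(nrow(unique(b[b$sex == "male", -1])), 1L)
  expect_equal(nrow(unique(b[b$sex == "female", -1])), 1L)
  expect_true(all(is.na(b$forehead[b$sex == "female"])))
  expect_null(simulate_phenotypes(sim_config(), 0, 0, seed = 1))
  only_f <- simulate_phenotypes(sim_config(), 0, 5, seed = 1)
  expect_equal(nrow(only_f), 5L)
})

test_that("phenotype draws hit their configured moments", {
  cfg <- sim_config()
  b <- simulate_phenotypes(cfg, 10000, 0, seed = 11)
  se <- cfg$phenotype_sds$male[["tarsus"]] / sqrt(10000)
  expect_lt(abs(mean(b$tarsus) - cfg$phenotype_means$male[["tarsus"]]), 3 * se)
  expect_true(all(b$age >= 1 & b$age <= cfg$age_max))
  # ~50% yearlings under the truncated geometric default
  expect_lt(abs(mean(b$age == 1) - 0.47), 0.03)
})

test_that("laying dates: zero effects and zero noise give the bare baseline", {
  ls <- line_season()
  cfg <- sim_config()
  cfg$phenology$male[] <- 0; cfg$phenology$female[] <- 0
  cfg$phenology$noise_sd <- 0
  d <- simulate_laying_dates(ls$nests, ls$birds, ls$tess, cfg, year_effect = 0,
                             seed = 3)
  expect_true(all(d == round(cfg$phenology$baseline)))
  bad <- ls$nests; bad$male_id[1] <- "GHOST"
  expect_error(simulate_laying_dates(bad, ls$birds, ls$tess, cfg), "missing phenotype")
})

test_that("wing length shortens the laying date (negative generating sign)", {
  cfg <- tiny_config(n_seasons = 1L, n_boxes = 120L)
  cfg$phenology$male[] <- 0
  cfg$phenology$male[["wing"]] <- -3
  cfg$phenology$female[] <- 0
  cfg$phenology$bird_sd_male <- 0; cfg$phenology$bird_sd_female <- 0
  cfg$phenology$noise_sd <- 0.5
  cfg$polygyny$unassisted_rate <- 0   # keep every nest's male identified
  pop <- simulate_population(cfg, seed = 21)
  b <- pop$birds[match(paste(pop$nests$year, pop$nests$male_id),
                       paste(pop$birds$year, pop$birds$bird_id)), ]
  expect_lt(cor(b$wing, pop$nests$laying_date), -0.3)
})

test_that("polygyny: impossible intercept means no polygynous males", {
  cfg <- tiny_config()
  cfg$polygyny$coeffs[["intercept"]] <- -50
  pop <- simulate_population(cfg, seed = 31)
  expect_false(any(pop$nests$female_status %in% c("primary", "secondary")))
})

test_that("generated seasons satisfy the breeding-record invariants", {
  cfg <- sim_config(n_seasons = 6L, n_boxes = 80L, extent = c(0, 2000, 0, 80))
  pop <- simulate_population(cfg, seed = 41)
  v <- validate_inputs(pop$nests, pop$birds,
                       season_window = c(cfg$season_start,
                                         cfg$season_start + cfg$season_length))
  expect_equal(nrow(v), 0L)
  # realized polygyny never beyond the configured neighbour order
  pr <- build_pair_data(pop, max_order = Inf)
  expect_true(all(pr$order[pr$response == 1] <= cfg$polygyny$max_order))
  # fitness invariants
  expect_true(all(pop$fitness$recruits <= pop$fitness$fledglings))
  expect_true(all(pop$fitness$recruits >= 0 & pop$fitness$grand_offspring >= 0))
})

test_that("end-to-end simulation is bit-reproducible under a seed", {
  cfg <- tiny_config()
  a <- simulate_population(cfg, seed = 77)
  b <- simulate_population(cfg, seed = 77)
  expect_identical(a$nests, b$nests)
  expect_identical(a$birds, b$birds)
  expect_identical(a$fitness, b$fitness)
  c2 <- simulate_population(cfg, seed = 78)
  expect_false(identical(a$nests$laying_date, c2$nests$laying_date))
})

test_that("fitness generator: degenerate mixtures and the Poisson limit of CMP", {
  rec <- data.frame(female_id = 1:4000, year = rep(1:4, 1000),
                    status = "monogamous", breeding_date = 145L,
                    fledglings = 6L)
  cfg <- sim_config()
  cfg$fitness$recruits$zi <- 1
  all0 <- simulate_fitness(rec, cfg, seed = 5)
  expect_true(all(all0$recruits == 0))
  cfg$fitness$recruits <- list(family = "cmp", intercept = log(1.2), primary = 0,
                               secondary = 0, date = 0, zi = 0, dispersion = 1,
                               year_sd = 0)
  pois <- simulate_fitness(rec, cfg, seed = 6)
  expect_lt(abs(var(pois$recruits) / mean(pois$recruits) - 1), 0.1)
})

test_that("population CSV round trip preserves the records", {
  pop <- simulate_population(tiny_config(), seed = 51)
  dir <- tempfile()
  write_population(pop, dir)
  expect_true(all(file.exists(file.path(dir, c("nests.csv", "birds.csv",
                                               "fitness.csv", "metadata.yaml")))))
  back <- read_population(dir)
  expect_equal(back$nests$laying_date, pop$nests$laying_date)
  expect_equal(back$fitness$recruits, pop$fitness$recruits)
  expect_equal(sort(names(back$tessellations)), sort(names(pop$tessellations)))
})
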