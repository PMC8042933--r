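# Zero-inflated count fitness models: likelihood correctness, oracle
# equivalences, AICc and the model-selection ladder.

fitness_records <- function(n_mono = 600, n_prim = 100, n_sec = 100,
                            n_years = 10, seed = 15, config = sim_config()) {
  rec <- data.frame(female_id = seq_len(n_mono + n_prim + n_sec),
                    year = rep_len(seq_len(n_years), n_mono + n_prim + n_sec),
                    status = rep(c("monogamous", "primary", "secondary"),
                                 c(n_mono, n_prim, n_sec)),
                    breeding_date = withr::with_seed(seed,
                      rnorm(n_mono + n_prim + n_sec, 145, 8)),
                    fledglings = 0L)
  simulate_fitness(rec, config, seed = seed + 1)
}

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  expect_equal(aicc(-100, 3, 1e9), 206, tolerance = 1e-5)
  expect_equal(aicc(-100, 0, 50), 200)
  expect_error(aicc(-10, 5, 6), "n > k")
  # ordering invariant under a common logLik shift
  l <- c(-100, -103, -98)
  d0 <- rank(sapply(l, aicc, k = 4, n = 60))
  d1 <- rank(sapply(l + 7, aicc, k = 4, n = 60))
  expect_identical(d0, d1)
})

test_that("poisson fit without extras equals the glm oracle exactly", {
  rec <- fitness_records()
  f <- fit_zi_count_glmm(rec, "recruits", family = "poisson", zi = FALSE,
                         random_year = FALSE)
  gl <- glm(recruits ~ status + scale(breeding_date), data = rec,
            family = poisson())
  expect_lt(max(abs(f$coefficients$estimate - unname(coef(gl)))), 1e-6)
  expect_equal(f$logLik, as.numeric(logLik(gl)), tolerance = 1e-8)
  expect_lt(max(abs(f$coefficients$se - unname(sqrt(diag(vcov(gl)))))), 1e-4)
})

test_that("reported logLik re-evaluates pointwise with independent pmf code", {
  rec <- fitness_records(n_mono = 300, n_prim = 60, n_sec = 60, n_years = 6)
  indep_ll <- function(fit, records, response) {
    y <- records[[response]]
    st <- factor(records$status, levels = c("monogamous", "primary", "secondary"))
    zd <- as.numeric(scale(records$breeding_date))
    X <- model.matrix(~ st + zd)
    eta <- drop(X %*% fit$coefficients$estimate)
    gh <- polynest:::gauss_hermite(9)
    sig <- sqrt(fit$year_variance)
    ll <- 0
    for (yr in unique(records$year)) {
      i <- records$year == yr
      contrib <- vapply(seq_along(gh$z), function(q) {
        mu <- exp(eta[i] + sig * gh$z[q])
        base <- switch(fit$family,
                       cmp = cmp_pmf(y[i], mu, fit$dispersion),
                       nbinom = dnbinom(y[i], mu = mu, size = fit$dispersion),
                       poisson = dpois(y[i], mu))
        sum(log(zi_pmf(y[i], fit$zi_prob, base)))
      }, numeric(1))
      m <- max(contrib + log(gh$w))
      ll <- ll + m + log(sum(exp(contrib + log(gh$w) - m)))
    }
    ll
  }
  for (fam in c("poisson", "nbinom", "cmp")) {
    f <- fit_zi_count_glmm(rec, "recruits", family = fam)
    expect_lt(abs(f$logLik - indep_ll(f, rec, "recruits")), 1e-6)
  }
})

test_that("likelihood at the optimum is no worse than at the generating truth", {
  cfg <- sim_config()
  rec <- fitness_records(config = cfg)
  f <- fit_zi_count_glmm(rec, "recruits", family = "cmp")
  gen <- cfg$fitness$recruits
  # likelihood of the generating parameters under the fitted model's code path
  truth <- c(gen$intercept, gen$primary, gen$secondary,
             gen$date * sd(rec$breeding_date) / sd(rec$breeding_date))
  refit_ll <- local({
    y <- rec$recruits
    st <- factor(rec$status, levels = c("monogamous", "primary", "secondary"))
    zd <- as.numeric(scale(rec$breeding_date))
    X <- model.matrix(~ st + zd)
    eta <- drop(X %*% truth)
    gh <- polynest:::gauss_hermite(9)
    ll <- 0
    for (yr in unique(rec$year)) {
      i <- rec$year == yr
      contrib <- vapply(seq_along(gh$z), function(q) {
        mu <- exp(eta[i] + gen$year_sd * gh$z[q])
        sum(log(zi_pmf(y[i], gen$zi, cmp_pmf(y[i], mu, gen$dispersion))))
      }, numeric(1))
      m <- max(contrib + log(gh$w))
      ll <- ll + m + log(sum(exp(contrib + log(gh$w) - m)))
    }
    ll
  })
  expect_gte(f$logLik, refit_ll - 1e-6)
})

test_that("zi-negative-binomial agrees with an independent mixed-model fitter", {
  skip_if_not_installed("glmmTMB")
  rec <- fitness_records(n_mono = 700, n_prim = 120, n_sec = 120, n_years = 8,
                         seed = 33)
  f <- fit_zi_count_glmm(rec, "grand_offspring", family = "nbinom")
  rec$fyear <- factor(rec$year)
  tmb <- suppressWarnings(glmmTMB::glmmTMB(
    grand_offspring ~ status + scale(breeding_date) + (1 | fyear),
    ziformula = ~1, family = glmmTMB::nbinom2(), data = rec))
  expect_lt(max(abs(f$coefficients$estimate -
                      unname(glmmTMB::fixef(tmb)$cond))), 5e-3)
  expect_lt(abs(f$zi_prob - plogis(unname(glmmTMB::fixef(tmb)$zi))), 5e-3)
  expect_lt(abs(log(f$dispersion) - log(stats::sigma(tmb))), 2e-2)
})

test_that("model selection ranks candidates and flags the best", {
  rec <- fitness_records(n_mono = 500, n_prim = 80, n_sec = 80, n_years = 8,
                         seed = 44)
  ms <- model_selection(rec, "recruits")
  expect_equal(ms$ladder$dAICc[1], 0)
  expect_equal(ms$ladder$rank[1], 1L)
  ok <- ms$ladder$note == ""
  expect_identical(sort(ms$ladder$rank[ok]), seq_len(sum(ok)))
  expect_equal(ms$best$aicc, min(ms$ladder$AICc[ok]))
  # k counts every estimated parameter: zi, dispersion and year variance
  krow <- ms$ladder[ms$ladder$family == "cmp" & ms$ladder$zi &
                      ms$ladder$random_year, ]
  expect_equal(krow$k, 4 + 1 + 1 + 1)
})

test_that("underdispersed zi-CMP data prefer a CMP kernel over Poisson", {
  cfg <- sim_config()
  cfg$fitness$recruits <- list(family = "cmp", intercept = log(1.8), primary = 0,
                               secondary = 0, date = 0, zi = 0.3,
                               dispersion = 2.5, year_sd = 0.1)
  wins <- 0L
  for (r in 1:8) {
    rec <- fitness_records(n_mono = 2000, n_prim = 10, n_sec = 10,
                           n_years = 10, seed = 200 + r, config = cfg)
    cand <- list(
      cmp = fit_zi_count_glmm(rec, "recruits", "cmp", zi = TRUE, random_year = TRUE),
      cmp0 = fit_zi_count_glmm(rec, "recruits", "cmp", zi = TRUE, random_year = FALSE),
      poi = fit_zi_count_glmm(rec, "recruits", "poisson", zi = TRUE, random_year = TRUE),
      poi0 = fit_zi_count_glmm(rec, "recruits", "poisson", zi = TRUE, random_year = FALSE))
    a <- vapply(cand, `[[`, 0, "aicc")
    if (min(a[1:2]) < min(a[3:4])) wins <- wins + 1L
  }
  expect_gte(wins, 7L)
})

test_that("plain Poisson data put the zero-inflation parameter at the boundary", {
  cfg <- sim_config()
  cfg$fitness$recruits <- list(family = "cmp", intercept = log(1.5), primary = 0,
                               secondary = 0, date = 0, zi = 0, dispersion = 1,
                               year_sd = 0.05)
  rec <- fitness_records(n_mono = 2300, n_prim = 10, n_sec = 10, n_years = 10,
                         seed = 55, config = cfg)
  with_zi <- fit_zi_count_glmm(rec, "recruits", "poisson", zi = TRUE,
                               random_year = FALSE)
  without <- fit_zi_count_glmm(rec, "recruits", "poisson", zi = FALSE,
                               random_year = FALSE)
  expect_lt(with_zi$zi_prob, 0.05)
  expect_lt(abs(with_zi$aicc - without$aicc), 2 + 0.1)
})

test_that("unassisted records are rejected until reclassified", {
  rec <- fitness_records(n_mono = 50, n_prim = 5, n_sec = 5, n_years = 3)
  rec$status[1] <- "unassisted"
  expect_error(fit_zi_count_glmm(rec, "recruits"), "reclassify_unassisted")
})
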