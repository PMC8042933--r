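## Standardization, orthogonal age polynomials, collinearity screening, the
## 15-term binomial mixed model for the probability of social polygyny, and
## the per-sex local-phenology mixed models.

#' Center and standardize predictor columns
#'
#' Replaces each column by `(x - mean) / sd` and records the transformation
#' so it can be reapplied to new data.
#'
#' @param data A data frame.
#' @param columns Character vector of numeric, non-constant columns.
#' @param spec Optional previously learned specification to reapply.
#' @return `list(data, spec)`; `spec` is a data frame with `column`, `mean`,
#'   `sd`.
#' @export
standardize <- function(data, columns, spec = NULL) {
  if (is.null(spec)) {
    mus <- vapply(columns, function(cc) mean(data[[cc]], na.rm = TRUE), numeric(1))
    sds <- vapply(columns, function(cc) stats::sd(data[[cc]], na.rm = TRUE), numeric(1))
    if (any(!is.finite(sds)) || any(sds <= 0))
      stop_bad_arg("zero-variance column(s): ",
                   paste(columns[!is.finite(sds) | sds <= 0], collapse = ", "))
    spec <- data.frame(column = columns, mean = mus, sd = sds,
                       stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(spec))) {
    cc <- spec$column[i]
    data[[cc]] <- (data[[cc]] - spec$mean[i]) / spec$sd[i]
  }
  list(data = data, spec = spec)
}

#' Orthogonal polynomial basis of degree 2
#'
#' Gram-Schmidt orthonormalization of `{x, x^2}` against the constant and
#' each other (the construction behind `stats::poly`), returning the basis
#' and the coefficients needed to evaluate it on new data.  The resulting
#' linear and quadratic columns are jointly interpretable but not
#' individually biological.
#'
#' @param x Numeric vector with at least 3 distinct values.
#' @param degree Polynomial degree (2).
#' @return `list(basis, coefs)`; `basis` has columns `deg1`, `deg2`.
#' @export
ortho_poly <- function(x, degree = 2L) {
  if (length(unique(x[!is.na(x)])) < degree + 1L)
    stop_bad_arg("ortho_poly() needs at least ", degree + 1L, " distinct values")
  p <- stats::poly(x[!is.na(x)], degree)
  basis <- matrix(NA_real_, length(x), degree,
                  dimnames = list(NULL, paste0("deg", seq_len(degree))))
  basis[!is.na(x), ] <- unclass(p)[, seq_len(degree)]
  list(basis = basis, coefs = attr(p, "coefs"))
}

ortho_poly_apply <- function(x, coefs) {
  out <- matrix(NA_real_, length(x), 2L)
  ok <- !is.na(x)
  out[ok, ] <- stats::poly(x[ok], 2L, coefs = coefs)[, 1:2]
  out
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing predictor j on all other
#' predictors (with intercept).  Values below ~2 indicate that collinearity
#' is not distorting the coefficients.
#'
#' @param X Numeric matrix or data frame of predictors (>= 2 columns).
#' @return Named vector of VIFs; exactly collinear columns get `Inf` with a
#'   warning.
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop_bad_arg("vif() needs at least 2 predictor columns")
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (rss / tss < 1e-12) Inf else 1 / (rss / tss)
  }, numeric(1))
  names(out) <- colnames(X)
  if (any(is.infinite(out)))
    warning("exact collinearity: ", paste(names(out)[is.infinite(out)], collapse = ", "))
  out
}

# The 15 fixed-effect terms of the polygyny model, in reporting order.
polygyny_terms <- function() {
  c("distance", "f_asyn", "f_nneigh", "f_tarsus", "f_age1", "f_age2", "f_wing",
    "m_asyn", "m_nneigh", "m_tarsus", "m_age1", "m_age2", "m_forehead",
    "m_blackness", "m_wing")
}

#' Build the standardized design matrix of the polygyny model
#'
#' Maps candidate-pair covariates to the 15 model terms: pair distance,
#' per-sex local asynchrony and number of neighbours, relative tarsus and
#' wing, an orthogonal quadratic basis of relative age (built per sex on the
#' rows being analysed), and the male ornaments.  All columns are centered
#' and standardized over the analysis rows; rows with missing covariates are
#' dropped listwise.
#'
#' @param pairs Candidate-pair rows from [build_pair_data()].
#' @param spec Optional `list(std, poly_m, poly_f)` from a previous call, to
#'   reuse a learned transformation.
#' @return `list(X, y, pairs, spec, n_dropped)`.
#' @export
build_polygyny_design <- function(pairs, spec = NULL) {
  need <- c("distance_m", "f_asyn", "f_nneigh", "f_rel_tarsus", "f_rel_age",
            "f_rel_wing", "m_asyn", "m_nneigh", "m_rel_tarsus", "m_rel_age",
            "m_rel_forehead", "m_rel_blackness", "m_rel_wing")
  ok <- stats::complete.cases(pairs[, need])
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) dropped at design construction (missing covariates)")
  pr <- pairs[ok, ]
  if (is.null(spec)) {
    pm <- ortho_poly(pr$m_rel_age); pf <- ortho_poly(pr$f_rel_age)
    spec <- list(poly_m = pm$coefs, poly_f = pf$coefs, std = NULL)
    bm <- pm$basis; bf <- pf$basis
  } else {
    bm <- ortho_poly_apply(pr$m_rel_age, spec$poly_m)
    bf <- ortho_poly_apply(pr$f_rel_age, spec$poly_f)
  }
  raw <- data.frame(distance = pr$distance_m,
                    f_asyn = pr$f_asyn, f_nneigh = pr$f_nneigh,
                    f_tarsus = pr$f_rel_tarsus, f_age1 = bf[, 1L], f_age2 = bf[, 2L],
                    f_wing = pr$f_rel_wing,
                    m_asyn = pr$m_asyn, m_nneigh = pr$m_nneigh,
                    m_tarsus = pr$m_rel_tarsus, m_age1 = bm[, 1L], m_age2 = bm[, 2L],
                    m_forehead = pr$m_rel_forehead, m_blackness = pr$m_rel_blackness,
                    m_wing = pr$m_rel_wing)
  st <- standardize(raw, polygyny_terms(), spec = spec$std)
  spec$std <- st$spec
  list(X = as.matrix(st$data), y = pr$response, pairs = pr, spec = spec,
       n_dropped = n_dropped)
}

new_polynest_fit <- function(kind, coefficients, ranef, logLik, n, converged,
                             singular = FALSE, model = NULL, note = NULL) {
  structure(list(kind = kind, coefficients = coefficients, ranef = ranef,
                 logLik = logLik, n = n, converged = converged,
                 singular = singular, model = model, note = note),
            class = "polynest_fit")
}

#' @export
print.polynest_fit <- function(x, digits = 3, ...) {
  cat(x$kind, "  (n =", x$n,
      if (!x$converged) " -- NOT CONVERGED" else "", ")\n", sep = "")
  if (!is.null(x$ranef) && nrow(x$ranef)) {
    cat("Random effects:\n")
    print(cbind(x$ranef[1L], round(x$ranef[-1L], digits)), row.names = FALSE)
  }
  cat("Fixed effects:\n")
  ct <- x$coefficients
  ct[-1L] <- lapply(ct[-1L], function(z) signif(z, digits))
  print(ct, row.names = FALSE)
  cat("logLik:", format(x$logLik, digits = 8), "\n")
  invisible(x)
}

#' Fit the binomial mixed model for the probability of social polygyny
#'
#' Logit-scale binomial GLMM of the candidate-pair response on the 15
#' standardized terms of [build_polygyny_design()], with crossed male and
#' female random intercepts, fitted by Laplace-approximated maximum
#' likelihood (lme4).  Season is deliberately not a random term.
#'
#' @param pairs Candidate-pair rows.
#' @param engine `"glmer"` (the mixed model) or `"glm"` (plain logistic
#'   regression without random intercepts, available as a degenerate
#'   reference).
#' @param design Optionally a precomputed [build_polygyny_design()] result.
#' @return A `polynest_fit` with coefficient table (estimate, SE, Wald z, p),
#'   random-intercept variances, log-likelihood and convergence flags.
#' @export
fit_polygyny_glmm <- function(pairs, engine = c("glmer", "glm"), design = NULL) {
  engine <- match.arg(engine)
  des <- design %||% build_polygyny_design(pairs)
  if (sum(des$y) == 0L || sum(des$y) == length(des$y))
    stop_bad_arg("degenerate response: all candidate pairs are ",
                 if (sum(des$y) == 0L) "0" else "1",
                 " (complete separation)")
  df <- data.frame(resp = des$y, des$X,
                   male_id = factor(des$pairs$male_id),
                   female_id = factor(des$pairs$female_id))
  if (engine == "glm") {
    fml <- stats::as.formula(paste("resp ~", paste(polygyny_terms(), collapse = " + ")))
    m <- stats::glm(fml, data = df, family = stats::binomial())
    sm <- summary(m)$coefficients
    ct <- data.frame(term = c("intercept", polygyny_terms()),
                     estimate = sm[, 1L], se = sm[, 2L], z = sm[, 3L], p = sm[, 4L],
                     row.names = NULL)
    return(new_polynest_fit("polygyny logistic regression (no random effects)",
                            ct, NULL, as.numeric(stats::logLik(m)), nrow(df),
                            m$converged, model = m))
  }
  fml <- stats::as.formula(paste("resp ~", paste(polygyny_terms(), collapse = " + "),
                                 "+ (1 | male_id) + (1 | female_id)"))
  m <- tryCatch(glmer_bounded(fml, df), error = function(e) e)
  if (inherits(m, "error")) {
    # the mixed fit failed outright (tiny or quasi-separated data): return the
    # fixed-effects-only fit, explicitly flagged as a failed mixed fit
    fb <- fit_polygyny_glmm(pairs, engine = "glm", design = des)
    fb$converged <- FALSE
    fb$note <- paste("mixed model failed:", conditionMessage(m),
                     "- fixed-effects-only fallback reported")
    warning(fb$note)
    return(fb)
  }
  sm <- summary(m)$coefficients
  vc <- as.data.frame(lme4::VarCorr(m))
  ct <- data.frame(term = c("intercept", polygyny_terms()),
                   estimate = sm[, 1L], se = sm[, 2L], z = sm[, 3L],
                   p = 2 * stats::pnorm(-abs(sm[, 3L])), row.names = NULL)
  re <- data.frame(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)
  conv <- length(m@optinfo$conv$lme4) == 0L && !isTRUE(attr(m, "theta_capped"))
  note <- if (isTRUE(attr(m, "theta_capped")))
    "random-intercept SD at its upper bound: Laplace surface degenerate for these data"
  new_polynest_fit("polygyny binomial GLMM (crossed male/female intercepts)",
                   ct, re, as.numeric(stats::logLik(m)), nrow(df), conv,
                   singular = lme4::isSingular(m), model = m, note = note)
}

# Laplace GLMM fit via the modular lme4 interface with the random-intercept
# parameters box-bounded.  Rare-event crossed binary data occasionally send
# the unbounded Laplace surface towards an infinite-variance ridge (the
# approximation, not the likelihood, improves there); capping the Cholesky
# parameters keeps the search in the region where the Laplace approximation
# is trustworthy, and a fit that ends on the cap is flagged.
glmer_bounded <- function(fml, df, theta_max = 3) {
  gf <- lme4::glFormula(fml, data = df, family = stats::binomial(),
                        control = lme4::glmerControl(calc.derivs = FALSE))
  devfun <- do.call(lme4::mkGlmerDevfun, gf)
  # the generated deviance function resolves lme4 helpers lexically, which
  # assumes lme4 is attached; make them visible in its environment
  environment(devfun)$GHrule <- lme4::GHrule
  devfun2 <- lme4::updateGlmerDevfun(devfun, gf$reTrms)
  rho <- environment(devfun2)
  nth <- length(gf$reTrms$theta)

  # Boundary check first: at theta = 0 the model is exactly the fixed-effects
  # GLM, whose coefficients are cheap and exact.  If the Laplace deviance
  # rises along every variance axis (and diagonal) from there, the optimum is
  # on the boundary and no iterative mixed optimization is needed -- which is
  # the typical outcome for rare-event candidate-pair data.
  X <- rho$pp$X
  glm0 <- stats::glm.fit(X, rho$resp$y, family = stats::binomial())
  beta0 <- glm0$coefficients
  d0 <- devfun2(c(rep(0, nth), beta0))
  # a probe where the inner PIRLS breaks down counts as a rise: the Laplace
  # approximation is unusable out there, not better
  dev_at <- function(th) tryCatch(devfun2(c(th, beta0)), error = function(e) Inf)
  # only a deviance improvement that could ever matter inferentially
  # (0.1 << the 3.84 of a chi^2_1 test) counts as leaving the boundary
  probe_dip <- function(ts) {
    for (t in ts) for (dir in seq_len(nth + 1L)) {
      th <- if (dir <= nth) replace(rep(0, nth), dir, t) else rep(t, nth)
      if (dev_at(th) <= d0 - 0.1) return(t)
    }
    0
  }
  boundary_fit <- function(note) {
    d0 <- devfun2(c(rep(0, nth), beta0))   # leave the state at the optimum
    res <- list(par = c(rep(0, nth), beta0), fval = d0, feval = 1L, conv = 0L,
                message = note, optimizer = "bobyqa")
    m <- lme4::mkMerMod(rho, res, gf$reTrms, fr = gf$fr)
    attr(m, "theta_capped") <- FALSE
    m
  }

  dip_local <- probe_dip(0.05)
  if (!dip_local) {
    dip_far <- probe_dip(c(0.5, 1.5, theta_max - 0.1))
    if (!dip_far) return(boundary_fit("boundary optimum (theta = 0)"))
    # the surface rises locally but falls far out: the sparse-binary Laplace
    # ridge, an artifact of the approximation; keep the local boundary
    # optimum and say so
    m <- boundary_fit(paste0("boundary optimum; distant Laplace ridge (theta ~ ",
                             dip_far, ") not followed"))
    return(m)
  }

  # genuine local improvement away from zero: bounded Laplace optimization.
  # A plausible small-variance optimum sits well below Cholesky scale 1; a
  # search that climbs to that cap has merged into the ridge and is flagged.
  # Inner-loop failures at hostile parameter values surface as huge
  # deviances so the search retreats instead of aborting.
  cap <- min(theta_max, 1)
  start <- c(rep(0.1, nth), beta0)
  np <- length(start)
  safe_dev <- function(p) tryCatch(devfun2(p), error = function(e) 1e10)
  opt <- minqa::bobyqa(start, safe_dev,
                       lower = c(rep(0, nth), rep(-Inf, np - nth)),
                       upper = c(rep(cap, nth), rep(Inf, np - nth)),
                       control = list(rhobeg = 0.05, rhoend = 1e-6,
                                      maxfun = 250L))
  fval <- devfun2(opt$par)                  # leave the state at the optimum
  res <- list(par = opt$par, fval = fval, feval = opt$feval,
              conv = if (opt$ierr > 0) opt$ierr else 0L, message = opt$msg,
              optimizer = "bobyqa")
  m <- lme4::mkMerMod(rho, res, gf$reTrms, fr = gf$fr)
  attr(m, "theta_capped") <- any(opt$par[seq_len(nth)] > cap - 1e-3)
  m
}

#' Fit a per-sex local-phenology mixed model
#'
#' Linear mixed model of a sex's local breeding asynchrony (days; positive =
#' later than the neighbourhood) on that sex's standardized relative traits,
#' with random intercepts for individual identity and year, fitted by REML.
#' Because the response is defined per candidate-pair row, rows repeat within
#' bird-years and the large degrees of freedom are those of the combination
#' dataset.
#'
#' @param pairs Candidate-pair rows.
#' @param sex `"male"` or `"female"`.
#' @param unit `"combination"` (default) fits one row per candidate
#'   combination, matching the candidate-pair analyses; because each
#'   bird-year's asynchrony value repeats across its combinations, the
#'   model-based standard errors of this design are strongly
#'   anti-conservative. `"individual"` keeps one row per bird and year at
#'   the direct (order-1) neighbourhood, which brings Wald calibration close
#'   to nominal (a mild residual inflation remains because neighbouring
#'   birds share the dates their asynchronies are computed against).
#' @return A `polynest_fit`; the `ranef` slot holds the individual, year and
#'   residual variance components.
#' @export
fit_phenology_lmm <- function(pairs, sex = c("male", "female"),
                              unit = c("combination", "individual")) {
  sex <- match.arg(sex)
  unit <- match.arg(unit)
  pre <- if (sex == "male") "m_" else "f_"
  if (unit == "individual") {
    pairs <- pairs[pairs$order == 1, ]
    key <- paste(pairs$year, pairs[[if (sex == "male") "male_id" else "female_id"]])
    pairs <- pairs[!duplicated(key), ]
  }
  traits <- if (sex == "male") c("tarsus", "age", "forehead", "blackness", "wing")
            else c("tarsus", "age", "wing")
  cols <- paste0(pre, "rel_", traits)
  need <- c(paste0(pre, "asyn"), cols)
  ok <- stats::complete.cases(pairs[, need])
  pr <- pairs[ok, ]
  pb <- ortho_poly(pr[[paste0(pre, "rel_age")]])
  raw <- data.frame(tarsus = pr[[paste0(pre, "rel_tarsus")]],
                    age1 = pb$basis[, 1L], age2 = pb$basis[, 2L],
                    wing = pr[[paste0(pre, "rel_wing")]])
  if (sex == "male") {
    raw$forehead <- pr$m_rel_forehead; raw$blackness <- pr$m_rel_blackness
  }
  terms <- if (sex == "male") c("tarsus", "age1", "age2", "forehead", "blackness", "wing")
           else c("tarsus", "age1", "age2", "wing")
  st <- standardize(raw, terms)
  df <- cbind(resp = pr[[paste0(pre, "asyn")]], st$data,
              id = factor(pr[[if (sex == "male") "male_id" else "female_id"]]),
              year = factor(pr$year))
  fml <- stats::as.formula(paste("resp ~", paste(terms, collapse = " + "),
                                 "+ (1 | id) + (1 | year)"))
  m <- lme4::lmer(fml, data = df, REML = TRUE,
                  control = lme4::lmerControl(calc.derivs = FALSE))
  sm <- summary(m)$coefficients
  vc <- as.data.frame(lme4::VarCorr(m))
  dfree <- nrow(df) - nrow(sm)
  ct <- data.frame(term = c("intercept", terms),
                   estimate = sm[, 1L], se = sm[, 2L], t = sm[, 3L],
                   df = dfree, p = 2 * stats::pt(-abs(sm[, 3L]), dfree),
                   row.names = NULL)
  re <- data.frame(group = c(vc$grp[vc$grp != "Residual"], "Residual"),
                   variance = c(vc$vcov[vc$grp != "Residual"],
                                vc$vcov[vc$grp == "Residual"]),
                   sd = c(vc$sdcor[vc$grp != "Residual"],
                          vc$sdcor[vc$grp == "Residual"]))
  conv <- length(m@optinfo$conv$lme4) == 0L
  new_polynest_fit(paste(sex, "local-phenology LMM (REML)"), ct, re,
                   as.numeric(stats::logLik(m)), nrow(df), conv,
                   singular = lme4::isSingular(m), model = m)
}
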