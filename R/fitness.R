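## Zero-inflated count regressions of female fitness on mating status.
##
## Responses (recruits, grand-offspring, fledglings) are modelled with a
## log-link count mean exp(intercept + status contrast + slope * standardized
## breeding date), an intercept-only zero-inflation mixture, an optional year
## random intercept, and a Poisson, Conway-Maxwell-Poisson or negative
## binomial kernel.  Fitting is direct maximum likelihood: the year intercept
## is integrated by Gauss-Hermite quadrature (years are few and the
## integrand is one-dimensional), the CMP mean parameterization is evaluated
## through a per-iteration spline of the mean-to-rate map, and standard
## errors come from the numerical Hessian at the optimum.  Candidate models
## are compared with AICc.

# Gauss-Hermite nodes/weights (physicists' convention) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix.
gauss_hermite <- function(q) {
  if (q == 1L) return(list(z = 0, w = 1))
  J <- diag(0, q)
  off <- sqrt(seq_len(q - 1L) / 2)
  J[cbind(1:(q - 1L), 2:q)] <- off
  J[cbind(2:q, 1:(q - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  # expectation over N(0,1): E f(Z) = sum w_i f(sqrt(2) x_i)
  list(z = sqrt(2) * e$values[ord], w = (e$vectors[1L, ord])^2)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`.
#'
#' @param logLik Maximized log-likelihood.
#' @param k Number of estimated parameters (including dispersion,
#'   zero-inflation and variance components).
#' @param n Number of observations; must exceed `k + 1`.
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop_bad_arg("AICc needs n > k + 1")
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# CMP quantities over a log-mean grid for one nu: splines of log lambda,
# log Z, the variance, and the moments of G = lgamma(y+1) that drive the
# nu-derivative of the log pmf.
cmp_grid <- function(lo, hi, nu) {
  grid <- seq(lo - 1e-6, hi + 1e-6, length.out = 81L)
  lam <- cmp_lambda_from_mu(exp(grid), nu)
  jmax <- cmp_trunc(lam, nu)
  j <- 0:jmax
  G <- lgamma(j + 1)
  lt <- outer(log(lam), j) - rep(nu * G, each = length(lam))
  mx <- apply(lt, 1L, max)
  w <- exp(lt - mx)
  sw <- rowSums(w)
  logZ <- mx + log(sw)
  m1 <- rowSums(w * rep(j, each = length(lam))) / sw
  m2 <- rowSums(w * rep(j^2, each = length(lam))) / sw
  EG <- rowSums(w * rep(G, each = length(lam))) / sw
  EjG <- rowSums(w * rep(j * G, each = length(lam))) / sw
  sf <- function(v) stats::splinefun(grid, v, method = "natural")
  list(llam = sf(log(lam)), lz = sf(logZ), var = sf(pmax(m2 - m1^2, 1e-10)),
       EG = sf(EG), covjG = sf(EjG - m1 * EG))
}

# log pmf matrix (n x length(shift)) for counts y at log-mean eta + shift,
# with its derivatives w.r.t. the log mean (A) and log dispersion (D).
count_logpmf <- function(y, eta, shift, family, disp, grad = FALSE) {
  lmu <- outer(eta, shift, `+`)
  inside <- lmu > -15 & lmu < 6
  lmu <- pmin(pmax(lmu, -15), 6)
  n <- length(y)
  mu <- exp(lmu)
  A <- D <- NULL
  if (family == "poisson") {
    lp <- y * lmu - mu - lgamma(y + 1)
    if (grad) A <- y - mu
  } else if (family == "nbinom") {
    lp <- matrix(stats::dnbinom(rep(y, ncol(lmu)), mu = mu, size = disp,
                                log = TRUE), n)
    if (grad) {
      A <- y - (y + disp) * mu / (mu + disp)
      D <- disp * (digamma(y + disp) - digamma(disp) + log(disp / (disp + mu)) +
                     1 - (y + disp) / (disp + mu))
    }
  } else if (family == "cmp_exact") {       # direct per-value mean inversion
    lam <- matrix(cmp_lambda_from_mu(as.vector(mu), disp), n)
    lz <- matrix(cmp_log_normalizer(as.vector(lam), disp), n)
    lp <- y * log(lam) - disp * lgamma(y + 1) - lz
  } else {                                  # cmp via log-mean grid splines
    gf <- cmp_grid(min(lmu), max(lmu), disp)
    lp <- y * matrix(gf$llam(lmu), n) - disp * lgamma(y + 1) - matrix(gf$lz(lmu), n)
    if (grad) {
      v <- matrix(gf$var(lmu), n)
      A <- (y - mu) * mu / v
      D <- disp * ((y - mu) * matrix(gf$covjG(lmu), n) / v -
                     (lgamma(y + 1) - matrix(gf$EG(lmu), n)))
    }
  }
  if (grad) A <- A * inside
  list(lp = lp, A = A, D = D)
}

# Zero-inflation mixture on the log scale, with derivatives: returns the
# mixed log pmf, the count-part posterior weight (multiplies A and D), and
# the derivative w.r.t. logit(pi).
zi_mix <- function(y, lp, logit_pi, grad = FALSE) {
  pi <- stats::plogis(logit_pi)
  lpi <- stats::plogis(logit_pi, log.p = TRUE)
  l1mpi <- stats::plogis(-logit_pi, log.p = TRUE)
  zero <- y == 0
  g <- l1mpi + lp
  wz <- NULL; dpi <- NULL
  if (grad) {
    wz <- matrix(1, nrow(lp), ncol(lp))
    dpi <- matrix(-pi, nrow(lp), ncol(lp))
  }
  if (any(zero)) {
    lz <- lp[zero, , drop = FALSE]
    m <- pmax(lpi, l1mpi + lz)
    mix <- m + log(exp(lpi - m) + exp(l1mpi + lz - m))
    g[zero, ] <- mix
    if (grad) {
      w <- exp(l1mpi + lz - mix)            # P(zero came from the count part)
      wz[zero, ] <- w
      p0 <- exp(lz)
      dpi[zero, ] <- pi * (1 - pi) * (1 - p0) / (pi + (1 - pi) * p0)
    }
  }
  list(g = g, wz = wz, dpi = dpi)
}

#' Fit a zero-inflated count mixed model of female fitness
#'
#' Maximum-likelihood fit of a fitness response on mating status (monogamous
#' is the reference level) and standardized breeding date, with intercept-only
#' zero inflation, optional year random intercept (integrated by adaptive-free
#' Gauss-Hermite quadrature) and a Poisson, CMP or negative-binomial kernel.
#'
#' @param records Fitness records with `status` (monogamous / primary /
#'   secondary), `year`, `breeding_date` and the response column.
#' @param response `"recruits"`, `"grand_offspring"` or `"fledglings"`.
#' @param family `"cmp"`, `"nbinom"` or `"poisson"`.
#' @param zi Include the zero-inflation mixture?
#' @param random_year Include the year random intercept?
#' @param gh_points Quadrature order for the year integral (the integrand is
#'   one-dimensional and close to Gaussian; 9 nodes are accurate to well below
#'   estimation error here).
#' @return An object of class `zi_count_fit`: count-part coefficient table,
#'   zero-inflation probability, dispersion, year variance, `logLik`, `AICc`,
#'   convergence and boundary flags.
#' @export
fit_zi_count_glmm <- function(records, response = "recruits",
                              family = c("cmp", "nbinom", "poisson"),
                              zi = TRUE, random_year = TRUE, gh_points = 9L) {
  family <- match.arg(family)
  statuses <- intersect(c("monogamous", "primary", "secondary"),
                        unique(records$status))
  if (!all(records$status %in% statuses))
    stop_bad_arg("records contain unassisted or unknown statuses; apply ",
                 "reclassify_unassisted() first")
  y <- records[[response]]
  if (any(y < 0) || any(y != floor(y))) stop_bad_arg("response must be counts")
  st <- factor(records$status, levels = statuses)
  dsd <- stats::sd(records$breeding_date)
  if (is.na(dsd) || dsd == 0) stop_bad_arg("breeding_date is constant")
  zdate <- (records$breeding_date - mean(records$breeding_date)) / dsd
  X <- stats::model.matrix(~ st + zdate)
  colnames(X) <- c("intercept", paste0(levels(st)[-1L], "_vs_monogamous"), "breeding_date")
  year <- factor(records$year)
  gh <- gauss_hermite(gh_points)
  n <- length(y)

  idx_beta <- seq_len(ncol(X))
  p0 <- stats::coef(stats::glm.fit(X, y, family = stats::poisson()))
  lower <- rep(-10, ncol(X)); upper <- rep(10, ncol(X))
  idx_pi <- idx_disp <- idx_sig <- integer(0)
  # moment-based starts: zero excess over the Poisson fit, variance/mean ratio
  mu_hat <- exp(pmin(drop(X %*% p0), 6))
  if (zi) {
    idx_pi <- length(p0) + 1L
    p_extra <- max(mean(y == 0) - mean(exp(-mu_hat)), 0.02)
    p0 <- c(p0, stats::qlogis(min(p_extra, 0.9)))
    lower <- c(lower, -12); upper <- c(upper, 8)
  }
  if (family != "poisson") {
    idx_disp <- length(p0) + 1L
    vmr <- stats::var(y) / max(mean(y), 1e-6)
    d0 <- if (family == "cmp") min(max(1 / vmr, 0.1), 5)
          else min(max(mean(y) / max(vmr - 1, 0.1), 0.1), 20)
    p0 <- c(p0, log(d0)); lower <- c(lower, log(0.02)); upper <- c(upper, log(50))
  }
  if (random_year) {
    idx_sig <- length(p0) + 1L
    p0 <- c(p0, log(0.1)); lower <- c(lower, log(1e-4)); upper <- c(upper, log(5))
  }

  yeari <- as.integer(year)
  eval_all <- function(p, grad, family_override = NULL) {
    eta <- drop(X %*% p[idx_beta])
    disp <- if (length(idx_disp)) exp(p[idx_disp]) else 1
    sigma <- if (length(idx_sig)) exp(p[idx_sig]) else 0
    shift <- if (length(idx_sig)) sigma * gh$z else 0
    cp <- count_logpmf(y, eta, shift, family_override %||% family, disp,
                       grad = grad)
    if (zi) {
      zm <- zi_mix(y, cp$lp, p[idx_pi], grad = grad)
      g <- zm$g
      if (grad) {
        cp$A <- cp$A * zm$wz
        if (!is.null(cp$D)) cp$D <- cp$D * zm$wz
        dpi <- zm$dpi
      }
    } else {
      g <- cp$lp
      dpi <- NULL
    }
    if (length(idx_sig)) {
      S <- rowsum(g, yeari)                     # years x nodes
      lw <- S + matrix(log(gh$w), nrow(S), length(gh$w), byrow = TRUE)
      m <- apply(lw, 1L, max)
      ll <- sum(m + log(rowSums(exp(lw - m))))
      if (!grad) return(list(nll = -ll))
      P <- exp(lw - m - log(rowSums(exp(lw - m))))  # posterior node weights
      W <- P[yeari, , drop = FALSE]
      gr <- numeric(length(p))
      aw <- rowSums(cp$A * W)
      gr[idx_beta] <- -colSums(X * aw)
      if (zi) gr[idx_pi] <- -sum(dpi * W)
      if (length(idx_disp)) gr[idx_disp] <- -sum(cp$D * W)
      gr[idx_sig] <- -sum((cp$A * W) %*% (sigma * gh$z))
      list(nll = -ll, grad = gr)
    } else {
      ll <- sum(g[, 1L])
      if (!grad) return(list(nll = -ll))
      gr <- numeric(length(p))
      gr[idx_beta] <- -colSums(X * cp$A[, 1L])
      if (zi) gr[idx_pi] <- -sum(dpi[, 1L])
      if (length(idx_disp)) gr[idx_disp] <- -sum(cp$D[, 1L])
      list(nll = -ll, grad = gr)
    }
  }
  # nlminb evaluates the objective and gradient at the same point; computing
  # both in one pass avoids rebuilding the CMP grid twice per iteration
  cache <- new.env(parent = emptyenv())
  cache$p <- NULL
  memo <- function(p) {
    if (!identical(p, cache$p)) {
      cache$r <- eval_all(p, grad = TRUE)
      cache$p <- p
    }
    cache$r
  }
  nll <- function(p) memo(p)$nll
  gfun <- function(p) memo(p)$grad

  opt <- stats::nlminb(p0, nll, gradient = gfun, lower = lower, upper = upper,
                       control = list(eval.max = 800, iter.max = 600,
                                      rel.tol = 1e-9))
  # the reported logLik is an exact evaluation at the optimum (the CMP branch
  # of the search path interpolates the mean-to-rate map)
  if (family == "cmp") {
    exact <- eval_all(opt$par, grad = FALSE, family_override = "cmp_exact")
    opt$objective <- exact$nll
  }
  # observed information from central differences of the analytic gradient
  H <- local({
    k <- length(opt$par)
    h <- pmax(1e-5, 1e-5 * abs(opt$par))
    J <- matrix(0, k, k)
    for (j in seq_len(k)) {
      pp <- pm <- opt$par
      pp[j] <- pp[j] + h[j]; pm[j] <- pm[j] - h[j]
      J[, j] <- (gfun(pp) - gfun(pm)) / (2 * h[j])
    }
    (J + t(J)) / 2
  })
  vc <- try(solve(H), silent = TRUE)
  se <- if (inherits(vc, "try-error")) rep(NA_real_, length(opt$par))
        else sqrt(pmax(diag(vc), 0))
  est <- opt$par
  k <- length(est)
  ll <- -opt$objective
  ct <- data.frame(term = colnames(X), estimate = est[idx_beta],
                   se = se[idx_beta], z = est[idx_beta] / se[idx_beta],
                   row.names = NULL)
  ct$p <- 2 * stats::pnorm(-abs(ct$z))
  boundary <- length(idx_sig) && est[idx_sig] <= lower[idx_sig] + 1e-6
  structure(list(kind = paste0(if (zi) "zero-inflated " else "", family,
                               " fitness model (", response, ")"),
                 response = response, family = family, zi = zi,
                 random_year = random_year,
                 coefficients = ct,
                 zi_prob = if (zi) stats::plogis(est[idx_pi]) else 0,
                 zi_logit = if (zi) est[idx_pi] else -Inf,
                 zi_logit_se = if (zi) se[idx_pi] else NA_real_,
                 dispersion = if (length(idx_disp)) exp(est[idx_disp]) else NA_real_,
                 year_variance = if (length(idx_sig)) exp(2 * est[idx_sig]) else NA_real_,
                 logLik = ll, k = k, n = n, aicc = aicc(ll, k, n),
                 converged = opt$convergence == 0, boundary = as.logical(boundary),
                 par = est, vcov = if (!inherits(vc, "try-error")) vc else NULL,
                 date_scale = c(center = mean(records$breeding_date), scale = dsd)),
            class = "zi_count_fit")
}

#' @export
print.zi_count_fit <- function(x, digits = 3, ...) {
  cat(x$kind, if (x$random_year) "+ year random intercept",
      if (!x$converged) "-- NOT CONVERGED", "\n")
  ct <- x$coefficients
  ct[-1L] <- lapply(ct[-1L], signif, digits)
  print(ct, row.names = FALSE)
  if (x$zi) cat("zero-inflation probability:", signif(x$zi_prob, digits), "\n")
  if (!is.na(x$dispersion)) cat("dispersion:", signif(x$dispersion, digits), "\n")
  if (!is.na(x$year_variance)) cat("year variance:", signif(x$year_variance, digits),
                                   if (x$boundary) "(boundary)", "\n")
  cat("logLik:", format(x$logLik, digits = 8), "  AICc:", round(x$aicc, 2),
      "  n:", x$n, "\n")
  invisible(x)
}

#' @export
logLik.zi_count_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' AICc ladder over candidate fitness-model structures
#'
#' Fits every combination of count kernel (Poisson, CMP, negative binomial),
#' zero inflation (with / without) and year random intercept (with /
#' without), and ranks the candidates by AICc.
#'
#' @inheritParams fit_zi_count_glmm
#' @param families,zi_opts,random_opts The candidate grid.
#' @return `list(ladder, fits)`; the ladder data frame has one row per
#'   converged candidate with `k`, `logLik`, `AICc`, `dAICc` and `rank`;
#'   non-converged candidates are kept with a reason and no rank.
#' @export
model_selection <- function(records, response = "recruits",
                            families = c("poisson", "cmp", "nbinom"),
                            zi_opts = c(FALSE, TRUE),
                            random_opts = c(FALSE, TRUE)) {
  grid <- expand.grid(family = families, zi = zi_opts, random_year = random_opts,
                      stringsAsFactors = FALSE)
  fits <- vector("list", nrow(grid)); reasons <- character(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    f <- try(fit_zi_count_glmm(records, response, family = grid$family[i],
                               zi = grid$zi[i], random_year = grid$random_year[i]),
             silent = TRUE)
    if (inherits(f, "try-error")) {
      reasons[i] <- conditionMessage(attr(f, "condition"))
    } else if (!f$converged) {
      reasons[i] <- "optimizer did not converge"; fits[[i]] <- f
    } else fits[[i]] <- f
  }
  ok <- reasons == ""
  if (!any(ok)) stop("no fitness-model candidate converged")
  ladder <- cbind(grid,
                  k = vapply(fits, function(f) if (is.null(f)) NA_integer_ else f$k, 0L),
                  logLik = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$logLik, 0),
                  AICc = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$aicc, 0))
  ladder$dAICc <- ladder$AICc - min(ladder$AICc[ok])
  ladder$rank <- NA_integer_
  ladder$rank[ok] <- rank(ladder$AICc[ok], ties.method = "first")
  ladder$note <- reasons
  best <- fits[[which(ok)[which.min(ladder$AICc[ok])]]]
  ord <- order(ladder$AICc)
  ladder <- ladder[ord, ]
  rownames(ladder) <- NULL
  list(ladder = ladder, fits = fits[ord], best = best)
}
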