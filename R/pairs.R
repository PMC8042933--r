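## Candidate-pair dataset: exhaustive male x female combinations per season,
## neighbourhood-relative covariates, and the 0/1 social-polygyny response.
##
## Every breeding male is combined with every breeding female of the same
## season except his own social mate (for a polygynous male: except his
## primary female -- his realized secondary is retained and is the row coded
## 1).  Unassisted females (no male ever observed provisioning) are excluded
## throughout.  For a combination at neighbour order k, covariates are
## computed against the inclusive order-k neighbourhood of each focal bird:
## relative traits (focal minus same-sex neighbourhood mean), local asynchrony
## (focal laying date minus neighbourhood mean date; positive = later than
## neighbours) and local density (number of neighbourhood territories).

# Nest-level tables used by the covariate computation: one male, one female
# and one laying date per territory.
season_nest_values <- function(nests, birds) {
  b <- birds[match(paste(nests$year, nests$male_id),
                   paste(birds$year, birds$bird_id)), ]
  f <- birds[match(paste(nests$year, nests$female_id),
                   paste(birds$year, birds$bird_id)), ]
  data.frame(nest_id = nests$nest_id,
             date = nests$laying_date,
             m_tarsus = b$tarsus, m_wing = b$wing, m_age = b$age,
             m_forehead = b$forehead, m_blackness = b$blackness,
             f_tarsus = f$tarsus, f_wing = f$wing, f_age = f$age,
             stringsAsFactors = FALSE)
}

#' Enumerate candidate male-female combinations for one season
#'
#' @param nests One season's nest table (columns `year`, `nest_id`, `x`, `y`,
#'   `laying_date`, `male_id`, `female_id`, `female_status`).
#' @param tess The season's [build_tessellation()] result.
#' @return A data frame with one row per candidate combination: ids, the nest
#'   of each bird (a polygynous male is located at his primary nest), the
#'   Euclidean distance between the two nests (m), the neighbour order of the
#'   two territories, and the response (1 for the realized polygynous
#'   male-secondary female combination, else 0).
#' @export
enumerate_candidate_pairs <- function(nests, tess) {
  stopifnot(length(unique(nests$year)) == 1L)
  if (anyDuplicated(nests$female_id))
    stop_bad_arg("a female appears on more than one nest")
  fem <- nests[nests$female_status != "unassisted", ]
  males <- nests[!is.na(nests$male_id), ]
  # focal nest of a male = his primary (or only) nest
  males <- males[order(match(males$female_status,
                             c("primary", "monogamous", "secondary"))), ]
  males <- males[!duplicated(males$male_id), ]
  if (nrow(males) == 0L || nrow(fem) == 0L)
    return(data.frame(year = integer(0), male_id = character(0),
                      female_id = character(0)))
  g <- expand.grid(mi = seq_len(nrow(males)), fi = seq_len(nrow(fem)),
                   KEEP.OUT.ATTRS = FALSE)
  pairs <- data.frame(year = males$year[g$mi],
                      male_id = males$male_id[g$mi],
                      female_id = fem$female_id[g$fi],
                      male_nest = males$nest_id[g$mi],
                      female_nest = fem$nest_id[g$fi],
                      f_status = fem$female_status[g$fi],
                      f_nest_male = fem$male_id[g$fi],
                      stringsAsFactors = FALSE)
  own <- !is.na(pairs$f_nest_male) & pairs$f_nest_male == pairs$male_id
  # drop the social pair (monogamous mate, or the primary of a polygynous
  # male); his realized secondary stays and is the response-1 row
  pairs <- pairs[!(own & pairs$f_status %in% c("monogamous", "primary")), ]
  own <- !is.na(pairs$f_nest_male) & pairs$f_nest_male == pairs$male_id
  pairs$response <- as.integer(own & pairs$f_status == "secondary")
  xy <- nests[match(pairs$male_nest, nests$nest_id), c("x", "y")]
  xy2 <- nests[match(pairs$female_nest, nests$nest_id), c("x", "y")]
  pairs$distance_m <- sqrt((xy$x - xy2$x)^2 + (xy$y - xy2$y)^2)
  pairs$order <- as.integer(tess$order[cbind(as.character(pairs$male_nest),
                                             as.character(pairs$female_nest))])
  pairs$f_nest_male <- NULL
  rownames(pairs) <- NULL
  pairs
}

#' Attach neighbourhood-relative covariates to candidate pairs
#'
#' For a combination at neighbour order k, each focal bird's neighbourhood is
#' its inclusive (order <= k) territory neighbourhood (`rule = "exact"` uses
#' order == k instead).  Covariates: local asynchrony in days (focal laying
#' date minus neighbourhood mean date; a polygynous male is dated by his
#' primary female's onset), number of neighbourhood territories, and relative
#' phenotypes (focal minus same-sex neighbourhood mean; one occupant per
#' territory, so a bigynous male contributes to a neighbourhood mean once per
#' territory held).  A focal bird's own territories never contribute to its
#' neighbourhood values.
#'
#' @param pairs Output of [enumerate_candidate_pairs()].
#' @param tess The season's tessellation.
#' @param nests,birds The season's nest and phenotype tables.
#' @param rule Neighbourhood rule, `"inclusive"` (default) or `"exact"`.
#' @param prospective_male If `TRUE`, the candidate female's territory is
#'   excluded from the male's neighbourhood means on every row, anticipating
#'   that a realized pairing makes it his second territory (the convention
#'   the generator draws events under, so that drawn and refitted covariates
#'   coincide on realized rows).  The analysis default (`FALSE`) excludes
#'   only territories the male actually holds.
#' @return `pairs` with covariate columns added; combinations whose
#'   neighbourhood is empty (or at infinite order) are dropped and counted in
#'   `attr(, "dropped")`.
#' @export
compute_local_covariates <- function(pairs, tess, nests, birds,
                                     rule = c("inclusive", "exact"),
                                     prospective_male = FALSE) {
  rule <- match.arg(rule)
  if (nrow(pairs) == 0L) return(pairs)
  nv <- season_nest_values(nests, birds)
  ids <- tess$ids
  nv <- nv[match(ids, nv$nest_id), ]
  O <- tess$order
  ks <- sort(unique(pairs$order[is.finite(pairs$order) & pairs$order >= 1L]))
  vals <- as.matrix(nv[, c("date", "m_tarsus", "m_wing", "m_age", "m_forehead",
                           "m_blackness", "f_tarsus", "f_wing", "f_age")])
  known <- !is.na(vals) * 1                  # unassisted nests have no known male
  vals0 <- ifelse(is.na(vals), 0, vals)
  # neighbourhood sums and per-column counts per (territory, k)
  sums <- list(); cnts <- list(); terr <- list()
  for (k in ks) {
    M <- if (rule == "inclusive") (O >= 1 & O <= k) * 1 else (O == k) * 1
    kk <- as.character(k)
    sums[[kk]] <- M %*% vals0
    cnts[[kk]] <- M %*% known
    terr[[kk]] <- rowSums(M)
  }
  keep <- pairs$order %in% ks
  pr <- pairs[keep, ]
  mi <- match(as.character(pr$male_nest), ids)
  fi <- match(as.character(pr$female_nest), ids)
  # per-row neighbourhood aggregates: one block subset per neighbour order
  nr <- nrow(pr); nc <- ncol(vals)
  mS <- matrix(0, nr, nc, dimnames = list(NULL, colnames(vals))); fS <- mS
  mC <- mS; fC <- mS
  m_terr <- numeric(nr); f_terr <- numeric(nr)
  for (k in as.character(ks)) {
    r <- pr$order == as.integer(k)
    mS[r, ] <- sums[[k]][mi[r], , drop = FALSE]
    mC[r, ] <- cnts[[k]][mi[r], , drop = FALSE]
    fS[r, ] <- sums[[k]][fi[r], , drop = FALSE]
    fC[r, ] <- cnts[[k]][fi[r], , drop = FALSE]
    m_terr[r] <- terr[[k]][mi[r]]
    f_terr[r] <- terr[[k]][fi[r]]
  }
  m_sum_date <- mS[, "date"]; m_n_date <- mC[, "date"]
  f_sum_date <- fS[, "date"]; f_n_date <- fC[, "date"]
  mcols <- c("m_tarsus", "m_wing", "m_age", "m_forehead", "m_blackness")
  fcols <- c("f_tarsus", "f_wing", "f_age")
  m_sums <- lapply(mcols, function(cc) mS[, cc]); names(m_sums) <- mcols
  m_cnts <- lapply(mcols, function(cc) mC[, cc]); names(m_cnts) <- mcols
  f_sums <- lapply(fcols, function(cc) fS[, cc]); names(f_sums) <- fcols
  f_cnts <- lapply(fcols, function(cc) fC[, cc]); names(f_cnts) <- fcols

  # prospective convention: the candidate female's territory (always at the
  # row's own order, hence inside the male's inclusive neighbourhood) is
  # removed from the male's means
  if (prospective_male && rule == "inclusive") {
    m_sum_date <- m_sum_date - vals0[fi, "date"]
    m_n_date <- m_n_date - known[fi, "date"]
    for (cc in mcols) {
      m_sums[[cc]] <- m_sums[[cc]] - vals0[fi, cc]
      m_cnts[[cc]] <- m_cnts[[cc]] - known[fi, cc]
    }
  }

  # a bigynous male's other territory never contributes to his own
  # neighbourhood means (the territory count is left as the plain
  # neighbourhood size)
  two <- unique(nests$male_id[duplicated(nests$male_id) & !is.na(nests$male_id)])
  for (m in two) {
    nest_m <- as.character(nests$nest_id[!is.na(nests$male_id) & nests$male_id == m])
    for (rr in which(pr$male_id == m)) {
      for (o in setdiff(nest_m, as.character(pr$male_nest[rr]))) {
        oi <- match(o, ids)
        korder <- O[mi[rr], oi]
        inn <- if (rule == "inclusive") korder >= 1 && korder <= pr$order[rr]
               else korder == pr$order[rr]
        if (!isTRUE(inn)) next
        m_sum_date[rr] <- m_sum_date[rr] - vals0[oi, "date"]
        m_n_date[rr] <- m_n_date[rr] - 1
        for (cc in mcols) {
          m_sums[[cc]][rr] <- m_sums[[cc]][rr] - vals0[oi, cc]
          m_cnts[[cc]][rr] <- m_cnts[[cc]][rr] - known[oi, cc]
        }
      }
    }
  }

  div <- function(s, n) ifelse(n > 0, s / n, NA_real_)
  out <- pr
  out$m_asyn <- vals[mi, "date"] - div(m_sum_date, m_n_date)
  out$f_asyn <- vals[fi, "date"] - div(f_sum_date, f_n_date)
  out$m_nneigh <- m_terr
  out$f_nneigh <- f_terr
  out$m_rel_tarsus <- vals[mi, "m_tarsus"] - div(m_sums$m_tarsus, m_cnts$m_tarsus)
  out$m_rel_wing <- vals[mi, "m_wing"] - div(m_sums$m_wing, m_cnts$m_wing)
  out$m_rel_age <- vals[mi, "m_age"] - div(m_sums$m_age, m_cnts$m_age)
  out$m_rel_forehead <- vals[mi, "m_forehead"] - div(m_sums$m_forehead, m_cnts$m_forehead)
  out$m_rel_blackness <- vals[mi, "m_blackness"] - div(m_sums$m_blackness, m_cnts$m_blackness)
  out$f_rel_tarsus <- vals[fi, "f_tarsus"] - div(f_sums$f_tarsus, f_cnts$f_tarsus)
  out$f_rel_wing <- vals[fi, "f_wing"] - div(f_sums$f_wing, f_cnts$f_wing)
  out$f_rel_age <- vals[fi, "f_age"] - div(f_sums$f_age, f_cnts$f_age)

  empty <- m_terr == 0 | f_terr == 0
  dropped <- sum(!keep) + sum(empty)
  if (any(empty)) out <- out[!empty, ]
  if (dropped > 0)
    message(dropped, " candidate combination(s) dropped (empty neighbourhood ",
            "or unreachable territory pair)")
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Restrict candidate pairs to close neighbour orders
#'
#' @param pairs Candidate-pair rows with an `order` column.
#' @param max_order Largest neighbour order retained (default 2: polygyny
#'   essentially never spans more than the two closest territories).  `Inf`
#'   keeps everything.
#' @return Filtered rows; `attr(, "retention")` holds kept/total counts.
#' @export
filter_by_order <- function(pairs, max_order = 2) {
  if (max_order < 1) stop_bad_arg("max_order must be >= 1")
  keep <- is.finite(pairs$order) & pairs$order <= max_order
  out <- pairs[keep, ]
  rownames(out) <- NULL
  attr(out, "retention") <- c(kept = sum(keep), total = length(keep))
  out
}

#' Reclassify unassisted females
#'
#' Females never observed with a provisioning male have an ambiguous mating
#' status.  The default (`"exclude"`) removes them from an analysis dataset;
#' `"as_secondary"` relabels them as secondary females (the less conservative
#' classification used in sensitivity analyses of the fitness comparisons).
#'
#' @param records A data frame with a `status` (or `female_status`) column.
#' @param mode `"exclude"` or `"as_secondary"`.
#' @return The reclassified data frame.  Both modes are idempotent.
#' @export
reclassify_unassisted <- function(records, mode = c("exclude", "as_secondary")) {
  mode <- match.arg(mode)
  col <- if ("status" %in% names(records)) "status" else "female_status"
  if (!col %in% names(records)) stop_bad_arg("no status column found")
  un <- records[[col]] == "unassisted"
  if (mode == "exclude") records <- records[!un, ] else records[[col]][un] <- "secondary"
  rownames(records) <- NULL
  records
}

#' Build the pooled candidate-pair dataset of a population
#'
#' Runs [enumerate_candidate_pairs()], [compute_local_covariates()] and
#' [filter_by_order()] for every season of a population and pools the rows.
#'
#' @param pop A `breeding_population` (see [simulate_population()]).
#' @param rule Neighbourhood rule passed to [compute_local_covariates()].
#' @param max_order Neighbour-order filter; `Inf` disables it.
#' @param prospective_male Passed to [compute_local_covariates()].
#' @return The pooled candidate-pair data frame.
#' @export
build_pair_data <- function(pop, rule = "inclusive", max_order = 2,
                            prospective_male = FALSE) {
  out <- lapply(sort(unique(pop$nests$year)), function(y) {
    nests <- pop$nests[pop$nests$year == y, ]
    birds <- pop$birds[pop$birds$year == y, ]
    tess <- pop$tessellations[[as.character(y)]]
    p <- enumerate_candidate_pairs(nests, tess)
    if (nrow(p) == 0L) return(NULL)
    # the order filter only reads the order column, so applying it before the
    # covariate pass avoids computing covariates for rows it would discard
    p <- filter_by_order(p, max_order)
    compute_local_covariates(p, tess, nests, birds, rule = rule,
                             prospective_male = prospective_male)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
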