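## End-to-end orchestration: simulate -> tessellate -> candidate pairs ->
## polygyny GLMM -> phenology LMMs -> fitness models (+ optional power), with
## every intermediate artifact written to one run directory.

fit_to_list <- function(fit) {
  if (inherits(fit, "zi_count_fit"))
    list(kind = fit$kind, coefficients = fit$coefficients,
         zi_prob = fit$zi_prob, dispersion = fit$dispersion,
         year_variance = fit$year_variance, logLik = fit$logLik, k = fit$k,
         n = fit$n, AICc = fit$aicc, converged = fit$converged,
         boundary = fit$boundary)
  else
    list(kind = fit$kind, coefficients = fit$coefficients, ranef = fit$ranef,
         logLik = fit$logLik, n = fit$n, converged = fit$converged,
         singular = fit$singular)
}

write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_to_list(fit), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

coef_table_md <- function(ct) {
  num <- vapply(ct, is.numeric, TRUE)
  ct[num] <- lapply(ct[num], function(z) formatC(z, digits = 3, format = "g"))
  header <- paste("|", paste(names(ct), collapse = " | "), "|")
  sep <- paste("|", paste(rep("---", ncol(ct)), collapse = " | "), "|")
  rows <- apply(ct, 1L, function(r) paste("|", paste(r, collapse = " | "), "|"))
  c(header, sep, rows)
}

#' Run the full analysis pipeline on a synthetic population
#'
#' Executes every stage in order and writes all artifacts to `out_dir`:
#' population CSVs, per-season territory GeoJSON and adjacency edge lists,
#' the candidate-pair table, JSON reports of the polygyny, phenology and
#' fitness fits, the AICc ladders, an optional power table, and a markdown
#' summary report.  Any stage failure aborts with the stage name; artifacts
#' written before the failure persist.
#'
#' @param config A [sim_config()].
#' @param out_dir Run directory (created; one directory per run is
#'   recommended).
#' @param seed Master seed for the whole run.
#' @param rule Neighbourhood rule for covariates.
#' @param max_order Neighbour-order filter for the candidate pairs.
#' @param classification `"exclude"` (drop unassisted females from fitness
#'   analyses) or `"as_secondary"`.
#' @param run_power Also run the reference power scenario?
#' @param power_reps Replicates for the power scenario.
#' @return Invisibly, a list with the population, pair data, fits, ladders
#'   and (optionally) power table.
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1L,
                         rule = "inclusive", max_order = 2,
                         classification = "exclude", run_power = FALSE,
                         power_reps = 100L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seeds <- derive_seeds(seed, 3L)
  pop <- stage("simulate", {
    p <- simulate_population(config, seed = seeds[[1L]])
    write_population(p, file.path(out_dir, "population"))
    p
  })
  stage("tessellate", {
    td <- file.path(out_dir, "territories")
    dir.create(td, showWarnings = FALSE)
    for (y in names(pop$tessellations)) {
      tessellation_to_geojson(pop$tessellations[[y]],
                              file.path(td, paste0("territories_", y, ".geojson")))
      utils::write.csv(pop$tessellations[[y]]$adjacency,
                       file.path(td, paste0("adjacency_", y, ".csv")),
                       row.names = FALSE)
    }
  })
  pairs <- stage("build-pairs", {
    pr <- build_pair_data(pop, rule = rule, max_order = max_order)
    out <- pr
    out$distance_m <- round(out$distance_m, 2)
    utils::write.csv(out, file.path(out_dir, "candidate_pairs.csv"), row.names = FALSE)
    pr
  })
  des <- build_polygyny_design(pairs)
  vifs <- stage("vif-screen", vif(des$X))
  poly_fit <- stage("fit-polygyny", {
    f <- fit_polygyny_glmm(pairs, design = des)
    write_fit_json(f, file.path(out_dir, "fit_polygyny.json"))
    f
  })
  phen <- stage("fit-phenology", {
    f <- list(male = fit_phenology_lmm(pairs, "male"),
              female = fit_phenology_lmm(pairs, "female"))
    write_fit_json(f$male, file.path(out_dir, "fit_phenology_male.json"))
    write_fit_json(f$female, file.path(out_dir, "fit_phenology_female.json"))
    f
  })
  fitness <- stage("fit-fitness", {
    rec <- reclassify_unassisted(pop$fitness, classification)
    fits <- list(recruits = fit_zi_count_glmm(rec, "recruits", family = "cmp"),
                 grand_offspring = fit_zi_count_glmm(rec, "grand_offspring",
                                                     family = "nbinom"))
    write_fit_json(fits$recruits, file.path(out_dir, "fit_recruits.json"))
    write_fit_json(fits$grand_offspring, file.path(out_dir, "fit_grand_offspring.json"))
    fits
  })
  ladder <- stage("model-selection", {
    rec <- reclassify_unassisted(pop$fitness, classification)
    ld <- model_selection(rec, "recruits")$ladder
    utils::write.csv(ld, file.path(out_dir, "aicc_ladder_recruits.csv"),
                     row.names = FALSE)
    ld
  })
  power <- NULL
  if (run_power) power <- stage("power", {
    pw <- estimate_power(power_scenario(reps = power_reps), seed = seeds[[2L]])
    utils::write.csv(pw, file.path(out_dir, "power.csv"), row.names = FALSE)
    pw
  })
  stage("report", {
    st <- table(pop$nests$female_status)
    md <- c("# Pipeline run report", "",
            paste("Seed:", seed), paste("Seasons:", length(unique(pop$nests$year))),
            paste("Female-nests:", nrow(pop$nests)),
            paste("Status counts:", paste(names(st), as.integer(st), collapse = ", ")),
            paste("Candidate pairs (order <=", max_order, "):", nrow(pairs)),
            paste("Max VIF:", round(max(vifs), 2)), "",
            "## Probability of social polygyny (binomial GLMM)", "",
            coef_table_md(poly_fit$coefficients), "",
            "## Male local phenology (LMM)", "",
            coef_table_md(phen$male$coefficients), "",
            "## Female local phenology (LMM)", "",
            coef_table_md(phen$female$coefficients), "",
            "## Fitness: recruits (zero-inflated CMP)", "",
            coef_table_md(fitness$recruits$coefficients), "",
            "## Fitness: grand-offspring (zero-inflated negative binomial)", "",
            coef_table_md(fitness$grand_offspring$coefficients))
    writeLines(md, file.path(out_dir, "report.md"))
    cfgf <- file.path(out_dir, "population", "config.yaml")
    yaml::write_yaml(list(seed = seed,
                          config_md5 = unname(tools::md5sum(cfgf)),
                          stages = c("simulate", "tessellate", "build-pairs",
                                     "fit-polygyny", "fit-phenology",
                                     "fit-fitness", "model-selection",
                                     if (run_power) "power", "report")),
                     file.path(out_dir, "metadata.yaml"))
  })
  invisible(list(population = pop, pairs = pairs, vif = vifs,
                 polygyny = poly_fit, phenology = phen, fitness = fitness,
                 ladder = ladder, power = power))
}

#' Validate breeding-record invariants
#'
#' Checks the structural invariants of a nests/birds dataset (synthetic or
#' field-derived): one nest per female and season, no male on more than two
#' nests, primary/secondary laying-date ordering for bigynous males, laying
#' dates inside the season window, and phenotype records for every referenced
#' bird.
#'
#' @param nests Nest table or path to a `nests.csv`.
#' @param birds Phenotype table or path to a `birds.csv`.
#' @param season_window Optional `c(first, last)` day-of-year bounds.
#' @return Data frame of violations (zero rows when the data are clean).
#' @export
validate_inputs <- function(nests, birds, season_window = NULL) {
  if (is.character(nests)) nests <- utils::read.csv(nests, stringsAsFactors = FALSE)
  if (is.character(birds)) birds <- utils::read.csv(birds, stringsAsFactors = FALSE)
  v <- list()
  flag <- function(rule, year, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, year = year, detail = detail)
  for (y in sort(unique(nests$year))) {
    nn <- nests[nests$year == y, ]
    dup_f <- unique(nn$female_id[duplicated(nn$female_id)])
    for (f in dup_f) flag("one nest per female", y, f)
    cnt <- table(nn$male_id[!is.na(nn$male_id)])
    for (m in names(cnt)[cnt > 2L]) flag("bigyny violated (male on >2 nests)", y, m)
    for (m in names(cnt)[cnt == 2L]) {
      two <- nn[!is.na(nn$male_id) & nn$male_id == m, ]
      two <- two[order(two$laying_date), ]
      okst <- identical(sort(two$female_status), c("primary", "secondary"))
      if (!okst) flag("bigynous male without primary+secondary statuses", y, m)
      else if (!(two$female_status[1L] == "primary" &&
                 two$laying_date[2L] > two$laying_date[1L]))
        flag("secondary must lay after primary", y, m)
    }
    ref <- setdiff(stats::na.omit(c(nn$male_id, nn$female_id)),
                   birds$bird_id[birds$year == y])
    for (b in ref) flag("bird without phenotype record", y, b)
    if (!is.null(season_window)) {
      out <- nn$nest_id[nn$laying_date < season_window[1L] |
                          nn$laying_date > season_window[2L]]
      for (id in out) flag("laying date outside season window", y, id)
    }
    st_bad <- nn$nest_id[!nn$female_status %in%
                           c("monogamous", "primary", "secondary", "unassisted")]
    for (id in st_bad) flag("unknown female status", y, id)
  }
  if (!length(v)) return(data.frame(rule = character(0), year = integer(0),
                                    detail = character(0)))
  out <- do.call(rbind, v)
  rownames(out) <- NULL
  out
}
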