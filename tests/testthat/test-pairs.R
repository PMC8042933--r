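# Candidate-pair enumeration, neighbourhood-relative covariates, order
# filtering and unassisted reclassification.

test_that("three monogamous pairs expand to 6 combinations, all response 0", {
  ls <- line_season()
  pairs <- enumerate_candidate_pairs(ls$nests, ls$tess)
  expect_equal(nrow(pairs), 6L)
  expect_true(all(pairs$response == 0L))
  # no male is paired with his own mate
  expect_false(any(paste(pairs$male_id, pairs$female_id) %in%
                     c("M1 F1", "M2 F2", "M3 F3")))
})

test_that("bigynous male season: hand-enumerated rows and a single response-1 row", {
  # M1 bigynous: primary P at nest A, secondary S at nest B; monogamous
  # (M2, F2) at C and (M3, F3) at D
  nests <- data.frame(year = 1L, nest_id = c("A", "B", "C", "D"),
                      x = c(0, 40, 80, 120), y = 0,
                      laying_date = c(121L, 128L, 125L, 131L),
                      male_id = c("M1", "M1", "M2", "M3"),
                      female_id = c("P", "S", "F2", "F3"),
                      female_status = c("primary", "secondary", "monogamous",
                                        "monogamous"),
                      stringsAsFactors = FALSE)
  birds <- data.frame(year = 1L,
                      bird_id = c("M1", "M2", "M3", "P", "S", "F2", "F3"),
                      sex = rep(c("male", "female"), c(3, 4)),
                      age = 2, tarsus = 19.5, wing = 79,
                      forehead = c(45, 45, 45, NA, NA, NA, NA),
                      blackness = c(55, 55, 55, NA, NA, NA, NA),
                      stringsAsFactors = FALSE)
  tess <- build_tessellation(data.frame(id = nests$nest_id, x = nests$x, y = nests$y))
  pairs <- enumerate_candidate_pairs(nests, tess)
  expect_equal(nrow(pairs), 9L)
  expect_setequal(paste(pairs$male_id, pairs$female_id),
                  c("M1 S", "M1 F2", "M1 F3",
                    "M2 P", "M2 S", "M2 F3",
                    "M3 P", "M3 S", "M3 F2"))
  expect_equal(sum(pairs$response), 1L)
  expect_equal(pairs$male_id[pairs$response == 1], "M1")
  expect_equal(pairs$female_id[pairs$response == 1], "S")
  # the bigynous male is located at his primary nest
  expect_true(all(pairs$male_nest[pairs$male_id == "M1"] == "A"))
})

test_that("unassisted females appear in no candidate row", {
  ls <- line_season()
  ls$nests$female_status[3] <- "unassisted"
  ls$nests$male_id[3] <- NA
  pairs <- enumerate_candidate_pairs(ls$nests, ls$tess)
  expect_false("F3" %in% pairs$female_id)
  expect_false(any(is.na(pairs$male_id)))
  expect_equal(nrow(pairs), 2L * 2L - 2L)  # 2 males x 2 females minus own mates
})

test_that("local covariates: asynchrony and relative traits from hand-computed means", {
  # focal middle nest B (male M2): direct neighbourhood = {A, C}
  ls <- line_season(dates = c(120L, 130L, 125L), m_tarsus = c(18, 20, 19))
  pairs <- enumerate_candidate_pairs(ls$nests, ls$tess)
  cov <- compute_local_covariates(pairs, ls$tess, ls$nests, ls$birds)
  r <- cov[cov$male_id == "M2" & cov$female_id == "F1", ]
  expect_equal(r$order, 1)
  # bred later than neighbourhood mean (120, 125)/2 = 122.5 -> +7.5
  expect_equal(r$m_asyn, 130 - 122.5)
  expect_equal(r$m_rel_tarsus, 20 - (18 + 19) / 2)
  expect_equal(r$m_nneigh, 2)
  # female at end nest A: her only direct neighbour is B
  expect_equal(r$f_asyn, 120 - 130)
  expect_equal(r$f_nneigh, 1)
})

test_that("homogeneous population gives identically zero relative covariates", {
  ls <- line_season(dates = c(125L, 125L, 125L), m_tarsus = c(19, 19, 19))
  ls$birds$tarsus <- 19.4; ls$birds$wing <- 78; ls$birds$age <- 2
  ls$birds$forehead[1:3] <- 45; ls$birds$blackness[1:3] <- 55
  cov <- compute_local_covariates(enumerate_candidate_pairs(ls$nests, ls$tess),
                                  ls$tess, ls$nests, ls$birds)
  for (cc in c("m_asyn", "f_asyn", "m_rel_tarsus", "m_rel_wing", "m_rel_age",
               "m_rel_forehead", "m_rel_blackness", "f_rel_tarsus",
               "f_rel_wing", "f_rel_age"))
    expect_true(all(cov[[cc]] == 0), label = cc)
})

test_that("covariates are invariant to constant shifts of traits and dates", {
  ls <- line_season()
  cov0 <- compute_local_covariates(enumerate_candidate_pairs(ls$nests, ls$tess),
                                   ls$tess, ls$nests, ls$birds)
  ls2 <- ls
  ls2$nests$laying_date <- ls2$nests$laying_date + 17L
  ls2$birds$tarsus <- ls2$birds$tarsus + 3
  cov1 <- compute_local_covariates(enumerate_candidate_pairs(ls2$nests, ls2$tess),
                                   ls2$tess, ls2$nests, ls2$birds)
  expect_equal(cov1$m_asyn, cov0$m_asyn)
  expect_equal(cov1$f_asyn, cov0$f_asyn)
  expect_equal(cov1$m_rel_tarsus, cov0$m_rel_tarsus)
  expect_equal(cov1$f_rel_tarsus, cov0$f_rel_tarsus)
})

test_that("inclusive and exact rules agree on order-1 rows only", {
  pop <- simulate_population(tiny_config(), seed = 91)
  y <- pop$nests$year[1]
  nests <- pop$nests[pop$nests$year == y, ]
  birds <- pop$birds[pop$birds$year == y, ]
  tess <- pop$tessellations[[as.character(y)]]
  pairs <- filter_by_order(enumerate_candidate_pairs(nests, tess), 2)
  inc <- compute_local_covariates(pairs, tess, nests, birds, rule = "inclusive")
  exa <- compute_local_covariates(pairs, tess, nests, birds, rule = "exact")
  o1 <- inc$order == 1
  expect_equal(inc$m_asyn[o1], exa$m_asyn[o1])
  expect_equal(inc$f_rel_tarsus[o1], exa$f_rel_tarsus[o1])
  o2 <- inc$order == 2
  expect_gt(max(abs(inc$m_asyn[o2] - exa$m_asyn[o2])), 0)
})

test_that("all-monogamous season of P pairs yields P*(P-1) rows before filtering", {
  cfg <- tiny_config()
  cfg$polygyny$coeffs[["intercept"]] <- -50   # polygyny probability ~ 0
  cfg$polygyny$unassisted_rate <- 0
  pop <- simulate_population(cfg, seed = 13)
  y <- pop$nests$year[1]
  nests <- pop$nests[pop$nests$year == y, ]
  P <- nrow(nests)
  tess <- pop$tessellations[[as.character(y)]]
  pairs <- enumerate_candidate_pairs(nests, tess)
  expect_equal(nrow(pairs), P * (P - 1L))
})

test_that("order filtering keeps only close combinations and logs retention", {
  pairs <- data.frame(order = c(1, 2, 3, 4), x = 1:4)
  kept <- filter_by_order(pairs, 2)
  expect_equal(kept$order, c(1, 2))
  expect_equal(unname(attr(kept, "retention")), c(2L, 4L))
  expect_equal(filter_by_order(pairs, Inf)$order, pairs$order)
  expect_error(filter_by_order(pairs, 0), "max_order")
})

test_that("unassisted reclassification excludes or relabels, idempotently", {
  rec <- data.frame(female_id = letters[1:6],
                    status = c("monogamous", "monogamous", "primary",
                               "secondary", "unassisted", "unassisted"))
  ex <- reclassify_unassisted(rec, "exclude")
  expect_equal(nrow(ex), 4L)
  expect_identical(reclassify_unassisted(ex, "exclude"), ex)
  sec <- reclassify_unassisted(rec, "as_secondary")
  expect_equal(sum(sec$status == "secondary"), 3L)
  expect_identical(reclassify_unassisted(sec, "as_secondary"), sec)
  expect_error(reclassify_unassisted(rec, "nope"))
})
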