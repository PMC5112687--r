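test_that("cut analysis reproduces hand-pruned recomputation on a toy forest", {
  f <- toy_forest()
  rep_ <- suppressWarnings(
    run_cut_analysis(f, outcomes = "hiv", estimators = "rds_ii", B = 20,
                     seed = 4, cuts = 0))
  expect_equal(rep_$cut_summary$n_remaining, c(4, 3))
  pruned <- prune_by_min_depth(f, 0)
  hand <- rds_ii(pruned, "hiv")$estimates
  got <- rep_$estimates[rep_$estimates$cut == ">0", ]
  expect_equal(stats::setNames(got$estimate, got$category), hand)
})

test_that("equal degrees make crude equal RDS-II at every cut, with containment", {
  f <- small_survey(seed = 11)
  fe <- rds_forest(transform(as.data.frame(f), degree = 5))
  rep_ <- run_cut_analysis(fe, outcomes = "hiv", estimators = "rds_ii",
                           B = 40, seed = 2, denominator = "non_missing")
  chk <- check_crude_within_cis(rep_)
  expect_true(all(chk$within))
  merged <- merge(rep_$estimates,
                  rep_$crude[, c("cut", "category", "estimate")],
                  by = c("cut", "category"), suffixes = c("", "_crude"))
  expect_equal(merged$estimate, merged$estimate_crude, tolerance = 1e-9)
})

test_that("sensitivity report has the full cut x outcome x estimator shape", {
  f <- small_survey(seed = 13)
  rep_ <- run_cut_analysis(f, outcomes = c("hiv", "idu"),
                           estimators = c("rds_i", "rds_ii", "rds_ss"),
                           N = 3000, B = 25, seed = 6)
  cuts_present <- unique(rep_$estimates$cut)
  expect_setequal(cuts_present, c("overall", ">0", ">1", ">2"))
  counts <- table(rep_$estimates$cut, rep_$estimates$outcome,
                  rep_$estimates$estimator)
  expect_true(all(counts == 2))  # two categories per binary outcome
  # n per cut matches the bookkeeping table
  for (ct in cuts_present) {
    n_ct <- rep_$cut_summary$n_remaining[rep_$cut_summary$cut == ct]
    expect_true(all(rep_$estimates$n_used[rep_$estimates$cut == ct] <= n_ct))
  }
  # containment booleans recompute from the stored values
  chk <- check_crude_within_cis(rep_)
  expect_identical(chk$within,
                   chk$crude >= chk$ci_low & chk$crude <= chk$ci_high)
})

test_that("an all-consuming cut is skipped while others proceed", {
  f <- toy_forest()  # max depth 2, so cut >2 leaves nothing
  rep_ <- suppressWarnings(
    run_cut_analysis(f, outcomes = "hiv", estimators = "rds_ii", B = 15,
                     seed = 9, cuts = c(0, 2)))
  expect_false(">2" %in% rep_$estimates$cut)
  expect_true(any(grepl("zero records", rep_$notes)))
  expect_true(">0" %in% rep_$estimates$cut)
})

test_that("seed-tree comparison is reproducible and respects the sign convention", {
  f <- small_survey(seed = 17)
  a <- compare_estimators_simulation(f, outcomes = "hiv",
                                     estimators = c("crude", "rds_ii"),
                                     replicates = 30, seed = 10)
  b <- compare_estimators_simulation(f, outcomes = "hiv",
                                     estimators = c("crude", "rds_ii"),
                                     replicates = 30, seed = 10)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$pairwise, b$pairwise)
  # sign convention: pair "X - Y" is mean(replicate X) - mean(replicate Y)
  d <- a$replicates[, "hiv", "crude"] - a$replicates[, "hiv", "rds_ii"]
  expect_equal(a$pairwise$mean_diff[a$pairwise$pair == "crude - rds_ii"],
               mean(d))
})

test_that("equal degrees force a degenerate crude/RDS-II comparison", {
  f <- small_survey(seed = 19)
  fe <- rds_forest(transform(as.data.frame(f), degree = 4))
  cmp <- compare_estimators_simulation(
    fe, outcomes = "hiv", estimators = c("crude", "rds_ii"),
    replicates = 25, seed = 3, denominator = "non_missing")
  row <- cmp$pairwise[cmp$pairwise$pair == "crude - rds_ii", ]
  expect_equal(row$mean_diff, 0, tolerance = 1e-12)
  expect_true(row$degenerate)
  expect_true(is.na(row$p_value))
})

test_that("RDS-SS and RDS-II differences vanish at astronomical N", {
  f <- small_survey(seed = 23)
  cmp <- compare_estimators_simulation(
    f, outcomes = "hiv", estimators = c("rds_ii", "rds_ss"),
    replicates = 20, seed = 8, N = 1e9)
  row <- cmp$pairwise[cmp$pairwise$pair == "rds_ii - rds_ss", ]
  expect_equal(round(abs(row$mean_diff), 1), 0)
  expect_lt(max(abs(cmp$replicates[, , "rds_ii"] -
                      cmp$replicates[, , "rds_ss"])), 0.05)
})

test_that("tree_fraction = 1 reproduces the full-sample estimate in every replicate", {
  f <- small_survey(seed = 29)
  cmp <- compare_estimators_simulation(
    f, outcomes = "hiv", estimators = c("crude", "rds_ii"),
    replicates = 5, tree_fraction = 1, seed = 12)
  full <- rds_ii(f, "hiv")$estimates
  cat1 <- cmp$config$categories[["hiv"]]
  expect_true(all(abs(cmp$replicates[, "hiv", "rds_ii"] -
                        full[cat1]) < 1e-9))
  expect_true(all(cmp$pairwise$degenerate | is.na(cmp$pairwise$p_value) |
                    cmp$pairwise$p_value >= 0))
})
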