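test_that("wave assignment follows recruiter links and is order-independent", {
  f <- toy_forest()
  expect_identical(stats::setNames(f$wave, f$id),
                   c(A = 0L, B = 1L, C = 2L, D = 0L))
  expect_identical(chain_depths(f), c(A = 2L, D = 0L))

  # shuffled row order gives the same waves
  df <- as.data.frame(f)[c(3, 1, 4, 2), c("id", "recruiter_id", "degree", "hiv")]
  f2 <- rds_forest(df)
  expect_identical(stats::setNames(f2$wave, f2$id)[sort(f2$id)],
                   stats::setNames(f$wave, f$id)[sort(f$id)])
})

test_that("all-blank recruiter column makes every record a seed", {
  f <- rds_forest(data.frame(id = letters[1:4], recruiter_id = "",
                             degree = 1, y = "x"))
  expect_true(all(f$wave == 0L))
  expect_identical(length(chain_depths(f)), 4L)
})

test_that("validation rejects malformed tables", {
  base <- data.frame(id = c("A", "B"), recruiter_id = c("", "A"),
                     degree = c(2, 3), y = c("u", "v"),
                     stringsAsFactors = FALSE)
  dup <- base; dup$id <- c("A", "A")
  expect_error(rds_forest(dup), "duplicate")
  self <- base; self$recruiter_id <- c("", "B")
  expect_error(rds_forest(self), "cycle")
  unk <- base; unk$recruiter_id <- c("", "Z")
  expect_error(rds_forest(unk), "unknown")
  cyc <- data.frame(id = c("A", "B"), recruiter_id = c("B", "A"),
                    degree = 1, y = "x")
  expect_error(rds_forest(cyc), "cycle")
  deg <- base; deg$degree <- c(0, 3)
  expect_error(rds_forest(deg), "degree")
  expect_warning(f <- rds_forest(deg, impute_degree = TRUE), "imputed")
  expect_true(all(f$degree >= 1))
})

test_that("pruning keeps whole chains by depth and nests across cuts", {
  f <- toy_forest()
  expect_identical(sort(prune_by_min_depth(f, 0)$id), c("A", "B", "C"))
  expect_identical(nrow(prune_by_min_depth(f, 2)), 0L)
  expect_identical(sort(prune_by_min_depth(f, 1)$id), c("A", "B", "C"))

  fs <- study_shape_forest()
  ns <- vapply(0:4, function(c) nrow(prune_by_min_depth(fs, c)), integer(1))
  expect_true(all(diff(ns) <= 0))
  for (c2 in 1:3)
    expect_true(all(prune_by_min_depth(fs, c2)$id %in%
                      prune_by_min_depth(fs, c2 - 1)$id))
  # chain sizes sum to n; seed count equals chain count
  expect_identical(sum(table(fs$seed_id)), 719L)
  expect_identical(length(chain_depths(fs)), sum(fs$wave == 0L))
})

test_that("cut_report reproduces the published bookkeeping arithmetic", {
  fs <- study_shape_forest()
  rep_ <- cut_report(fs)
  expect_equal(rep_$n_remaining, c(719, 669, 594, 537))
  expect_equal(rep_$n_seeds, c(119, 69, 37, 25))
  expect_equal(rep_$seeds_pct_of_sample, c(16.6, 10.3, 6.2, 4.7))
  expect_equal(rep_$n_removed_vs_overall, c(0, 50, 125, 182))
  expect_equal(rep_$removed_pct_of_overall, c(0, 7.0, 17.4, 25.3))
  expect_equal(rep_$wave_mean, c(208 / 119, 208 / 69, 176 / 37, 152 / 25),
               tolerance = 1e-12)
  expect_equal(rep_$wave_min, c(0, 1, 2, 3))
  expect_equal(rep_$wave_max, rep(16, 4))
  # identical cut removes nothing
  same <- cut_report(fs, cut_forests = list(`0` = fs))
  expect_equal(same$n_removed_vs_overall[2], 0)
  expect_equal(same$removed_pct_of_overall[2], 0)
  # non-subset cut forest is a consistency error
  other <- toy_forest()
  expect_error(cut_report(fs, cut_forests = list(`0` = other)),
               "subset")
})

test_that("display percents round half away from zero to one decimal", {
  expect_equal(rdsforest:::round_half_out(100 * 50 / 719), 7.0)
  expect_equal(rdsforest:::round_half_out(100 * 119 / 719), 16.6)
  expect_equal(rdsforest:::round_half_out(0.25, 1), 0.3)
  expect_equal(rdsforest:::round_half_out(-0.25, 1), -0.3)
})

test_that("CSV round trip is lossless including missing cells", {
  f <- toy_forest()
  df <- as.data.frame(f)
  df$hiv[2] <- NA
  f <- rds_forest(df[, c("id", "recruiter_id", "degree", "hiv")])
  path <- withr::local_tempfile(fileext = ".csv")
  write_recruitment_table(f, path)
  f2 <- read_recruitment_table(path)
  expect_identical(as.data.frame(f), as.data.frame(f2))
  expect_true(is.na(f2$hiv[f2$id == "B"]))
  # literal "seed" marker accepted
  raw <- utils::read.csv(path, colClasses = "character")
  raw$recruiter_id[raw$id == "A"] <- "seed"
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  expect_identical(read_recruitment_table(path)$wave, f$wave)
  # empty table round trips to header-only
  empty <- rds_forest(data.frame(id = character(), recruiter_id = character(),
                                 degree = numeric(), y = character()))
  write_recruitment_table(empty, path)
  expect_identical(nrow(read_recruitment_table(path)), 0L)
})

test_that("edge list export covers exactly the non-seed records", {
  f <- toy_forest()
  el <- export_edge_list(f)
  expect_identical(el, data.frame(child = c("B", "C"), parent = c("A", "B"),
                                  stringsAsFactors = FALSE))
})
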