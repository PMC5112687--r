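make_pair_forest <- function(pairs, degrees = NULL) {
  # pairs: 2-column matrix of recruiter/recruit outcome labels; builds one
  # star chain per pair plus a shared seed per recruiter label.
  n <- nrow(pairs)
  ids <- paste0("r", seq_len(n))
  kid <- paste0("k", seq_len(n))
  df <- data.frame(
    id = c(ids, kid),
    recruiter_id = c(rep("", n), ids),
    degree = degrees %||% 2,
    y = c(pairs[, 1], pairs[, 2]),
    stringsAsFactors = FALSE)
  rds_forest(df)
}

test_that("transition counts, probabilities and equilibrium match hand solutions", {
  # pos->neg x2, neg->pos x1, neg->neg x1 gives T = [[0,1],[.5,.5]],
  # e = (1/3, 2/3) ordered (neg, pos): e.T = e solved by hand.
  pairs <- rbind(c("pos", "neg"), c("pos", "neg"),
                 c("neg", "pos"), c("neg", "neg"))
  f <- make_pair_forest(pairs)
  m <- build_transition_model(f, "y", smoothed = FALSE)
  expect_equal(m$counts, matrix(c(1, 2, 1, 0), 2,
                                dimnames = list(c("neg", "pos"),
                                                c("neg", "pos"))))
  expect_equal(m$probs["pos", ], c(neg = 1, pos = 0))
  expect_equal(m$probs["neg", ], c(neg = 0.5, pos = 0.5))
  expect_equal(m$equilibrium, c(neg = 2 / 3, pos = 1 / 3), tolerance = 1e-10)
})

test_that("symmetric counts with equal row sums give a uniform equilibrium", {
  pairs <- rbind(c("a", "b"), c("b", "a"), c("a", "a"), c("b", "b"))
  m <- build_transition_model(make_pair_forest(pairs), "y", smoothed = FALSE)
  expect_equal(unname(m$equilibrium), c(0.5, 0.5), tolerance = 1e-10)
  # smoothing of an already-reciprocal model changes nothing
  ms <- build_transition_model(make_pair_forest(pairs), "y", smoothed = TRUE)
  expect_equal(ms$probs, m$probs, tolerance = 1e-10)
  expect_equal(ms$equilibrium, m$equilibrium, tolerance = 1e-10)
})

test_that("all pairs within one group flags a degenerate equilibrium", {
  pairs <- rbind(c("a", "a"), c("a", "a"))
  df <- data.frame(id = c("r1", "r2", "k1", "k2", "lone"),
                   recruiter_id = c("", "", "r1", "r2", ""),
                   degree = 2, y = c("a", "a", "a", "a", "b"))
  expect_warning(m <- build_transition_model(rds_forest(df), "y",
                                             smoothed = FALSE),
                 "never observed recruiting")
  expect_true(m$flags$degenerate)
  expect_true("b" %in% m$flags$zero_rows)
})

test_that("rds_i evaluates the equilibrium/harmonic-degree formula", {
  # T = [[0,1],[.5,.5]] on (pos, neg) with harmonic degrees (2, 4):
  # e = (1/3, 2/3), e/D = (1/6, 1/6) -> 50/50.
  pairs <- rbind(c("pos", "neg"), c("pos", "neg"),
                 c("neg", "pos"), c("neg", "neg"))
  # recruiters pos have degree 2... set degrees so group harmonic means are
  # pos: 2, neg: 4 (degrees constant within group).
  f <- make_pair_forest(pairs)
  df <- as.data.frame(f)
  df$degree <- ifelse(df$y == "pos", 2, 4)
  f <- rds_forest(df[, c("id", "recruiter_id", "degree", "y")])
  est <- rds_i(f, "y", smoothed = FALSE)
  expect_equal(est$estimates, c(neg = 50, pos = 50), tolerance = 1e-9)

  # equal harmonic degrees: estimate equals the equilibrium
  df$degree <- 3
  f3 <- rds_forest(df[, c("id", "recruiter_id", "degree", "y")])
  m <- build_transition_model(f3, "y", smoothed = FALSE)
  expect_equal(rds_i(f3, "y", smoothed = FALSE)$estimates / 100,
               m$equilibrium, tolerance = 1e-9)
})

test_that("two-group closed form agrees with the general formula", {
  set.seed(33)
  for (rep in 1:15) {
    n <- 40
    lab <- c("A", "B")
    pairs <- cbind(sample(lab, n, TRUE), sample(lab, n, TRUE))
    degs <- sample(1:9, 2 * n, TRUE)
    f <- make_pair_forest(pairs, degrees = degs)
    m <- build_transition_model(f, "y", smoothed = FALSE)
    if (m$counts["A", "B"] + m$counts["B", "A"] == 0) next
    est <- rds_i(f, "y", smoothed = FALSE)$estimates
    cf <- rdsforest:::rds_i_two_group(
      m$probs["A", "B"], m$probs["B", "A"],
      m$harmonic_degrees["A"], m$harmonic_degrees["B"])
    expect_equal(unname(est[c("A", "B")]), unname(cf), tolerance = 1e-9)
  }
})

test_that("rds_i refuses groups absent from all recruitment pairs", {
  df <- data.frame(id = c("r1", "k1", "lone"),
                   recruiter_id = c("", "r1", ""),
                   degree = 2, y = c("a", "a", "b"))
  suppressWarnings(
    expect_error(rds_i(rds_forest(df), "y"), "absent from all recruitment"))
})

test_that("missing outcomes are excluded from pairs and estimation", {
  df <- data.frame(id = c("s", "m", "k", "t"),
                   recruiter_id = c("", "s", "m", "k"),
                   degree = 2, y = c("a", NA, "b", "a"))
  f <- rds_forest(df)
  suppressWarnings(m <- build_transition_model(f, "y", smoothed = FALSE))
  expect_equal(sum(m$counts), 1)  # only k->t is a complete pair
  expect_equal(rds_ii(f, "y")$n_used, 3)
})
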