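test_that("convergence series ends at the full-sample estimate and flattens for constant outcomes", {
  f <- small_survey(seed = 21)
  s <- convergence_series(f, "hiv", estimator = "rds_ii")
  full <- rds_ii(f, "hiv")$estimates[attr(s, "category")]
  expect_equal(tail(s$value, 1), unname(full), tolerance = 1e-12)
  expect_true(all(diff(s$k) > 0))

  cons <- rds_forest(data.frame(id = as.character(1:15),
                                recruiter_id = c("", as.character(1:14)),
                                degree = 2, y = "pos"))
  sc <- convergence_series(cons, "y")
  expect_true(all(sc$value == 100))
})

test_that("crude prefix series matches hand prefix counts", {
  # enrollment order fixed via enroll_order; crude prefix percentages are
  # cumulative counts over k
  df <- data.frame(id = letters[1:6],
                   recruiter_id = c("", "a", "b", "", "d", "e"),
                   degree = 2, enroll_order = 1:6,
                   y = c("p", "p", "n", "p", "n", "n"))
  f <- rds_forest(df)
  s <- convergence_series(f, "y", estimator = "crude", category = "p",
                          k_min = 2)
  expect_equal(s$k, 2:6)
  expect_equal(s$value, 100 * c(2/2, 2/3, 3/4, 3/5, 3/6))
})

test_that("bottleneck series are per-chain and depend only on that chain", {
  # single chain: identical to the overall convergence series
  df <- data.frame(id = as.character(1:14),
                   recruiter_id = c("", as.character(1:13)),
                   degree = sample(1:5, 14, replace = TRUE),
                   y = rep(c("p", "n"), 7))
  f <- rds_forest(df)
  bs <- bottleneck_series(f, "y")
  expect_length(bs, 1)
  cs <- convergence_series(f, "y")
  expect_equal(bs[[1]]$value, cs$value)

  # two chains with opposite constant outcomes: flat 100% and 0% series
  mk <- function(pref, val) data.frame(
    id = paste0(pref, 1:12),
    recruiter_id = c("", paste0(pref, 1:11)),
    degree = 2, y = val)
  f2 <- rds_forest(rbind(mk("a", "p"), mk("b", "n")))
  b2 <- bottleneck_series(f2, "y", category = "p")
  finals <- vapply(b2, function(s) attr(s, "final"), numeric(1))
  expect_setequal(unname(finals), c(100, 0))
  expect_true(all(b2[[1]]$value %in% c(0, 100)))

  # short chains are skipped with a notice
  f3 <- rds_forest(rbind(mk("a", "p"),
                         data.frame(id = "z", recruiter_id = "",
                                    degree = 2, y = "n")))
  expect_message(b3 <- bottleneck_series(f3, "y"), "skipped")
  expect_identical(attr(b3, "skipped_chains"), "z")
})

test_that("homophily index matches direct substitution and its bounds", {
  m <- structure(list(outcome = "y", groups = c("a", "b"),
                      probs = matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))),
                      equilibrium = c(a = 0.5, b = 0.5),
                      homophily = rdsforest:::homophily_from(
                        matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE),
                        c(a = 0.5, b = 0.5))),
                 class = "rds_transition_model")
  expect_equal(homophily_index(m), c(a = 0.8, b = 0.8))
  # T[g,g] = e_g gives 0; T[g,g] = 1 gives 1; full avoidance gives -1
  expect_equal(unname(rdsforest:::homophily_from(
    matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE), c(0.3, 0.7))), c(0, 0))
  expect_equal(unname(rdsforest:::homophily_from(
    matrix(c(1, 0, 0, 1), 2), c(0.5, 0.5))), c(1, 1))
  expect_equal(unname(rdsforest:::homophily_from(
    matrix(c(0, 1, 1, 0), 2), c(0.5, 0.5))), c(-1, -1))
  # degenerate equilibrium: undefined
  expect_true(all(is.na(rdsforest:::homophily_from(
    matrix(c(1, 0, 1, 0), 2, byrow = TRUE), c(1, 0)))))
})

test_that("waves to equilibrium match the closed form and brute-force iteration", {
  T2 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  m <- structure(list(outcome = "y", groups = c("a", "b"), probs = T2,
                      equilibrium = c(a = 0.5, b = 0.5)),
                 class = "rds_transition_model")
  # degenerate start: distance after w waves is 0.5 * 0.8^w; < 0.01 first
  # at w = 18
  r <- equilibrium_waves(m, epsilon = 0.01, start = "worst_case")
  expect_equal(unname(r$waves), c(18, 18))
  expect_equal(r$waves_max, 18)
  # monotone in epsilon
  r5 <- equilibrium_waves(m, epsilon = 0.5, start = "worst_case")
  expect_lt(r5$waves_max, r$waves_max)

  # one-step mixing: all rows equal
  Tu <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, byrow = TRUE,
               dimnames = list(c("a", "b"), c("a", "b")))
  mu_ <- structure(list(outcome = "y", groups = c("a", "b"), probs = Tu,
                        equilibrium = c(a = 0.3, b = 0.7)),
                   class = "rds_transition_model")
  expect_equal(equilibrium_waves(mu_, 0.01)$waves_max, 1)

  # brute-force agreement on random ergodic matrices up to 5 groups
  set.seed(55)
  for (rep in 1:10) {
    G <- sample(2:5, 1)
    T_ <- matrix(stats::rgamma(G * G, 1) + 0.05, G)
    T_ <- T_ / rowSums(T_)
    dimnames(T_) <- list(letters[1:G], letters[1:G])
    e <- rdsforest:::stationary_dist(T_)
    mm <- structure(list(outcome = "y", groups = letters[1:G], probs = T_,
                         equilibrium = e),
                    class = "rds_transition_model")
    eps <- runif(1, 0.005, 0.1)
    got <- equilibrium_waves(mm, eps)$waves
    brute <- vapply(seq_len(G), function(g) {
      v <- numeric(G); v[g] <- 1
      w <- 0
      while (max(abs(v - e)) >= eps) {
        v <- as.vector(v %*% T_)
        w <- w + 1
      }
      w
    }, numeric(1))
    expect_equal(unname(got), brute)
  }

  # reducible chain: reports Inf with a diagnosis
  Tr <- matrix(c(1, 0, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  mr <- structure(list(outcome = "y", groups = c("a", "b"), probs = Tr,
                       equilibrium = c(a = 1, b = 0)),
                  class = "rds_transition_model")
  rr <- equilibrium_waves(mr, 0.01, max_waves = 50)
  expect_true(is.infinite(rr$waves_max))
  expect_false(is.na(rr$diagnosis))
})

test_that("series tables are tidy and exportable", {
  f <- small_survey(seed = 31)
  s <- convergence_series(f, "hiv")
  tab <- series_table(s)
  expect_named(tab, c("outcome", "estimator", "category", "seed_id", "k",
                      "value"))
  b <- suppressMessages(bottleneck_series(f, "hiv"))
  tb <- series_table(b)
  expect_true(all(tb$seed_id %in% f$seed_id))
})
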