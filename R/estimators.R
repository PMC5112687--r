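# Prevalence estimators: crude proportions, the inverse-degree (Volz-
# Heckathorn) RDS-II estimator, and the successive-sampling RDS-SS
# estimator with its deterministic expected-depletion inclusion
# probabilities. The Salganik-Heckathorn RDS-I estimator lives in
# transition.R next to the recruitment Markov model it is built on.

new_rds_estimate <- function(estimator, outcome, estimates, weights = NULL,
                             n_used = NA_integer_, ci_low = NULL,
                             ci_high = NULL, B = NULL, seed = NULL,
                             details = list()) {
  structure(list(estimator = estimator, outcome = outcome,
                 estimates = estimates, weights = weights, n_used = n_used,
                 ci_low = ci_low, ci_high = ci_high, B = B, seed = seed,
                 details = details),
            class = "rds_estimate")
}

#' @export
print.rds_estimate <- function(x, ...) {
  cat(sprintf("<rds_estimate> %s for outcome '%s' (n = %d)\n",
              x$estimator, x$outcome, x$n_used))
  tab <- data.frame(category = names(x$estimates),
                    estimate = round(x$estimates, 2))
  if (!is.null(x$ci_low)) {
    tab$ci_low <- round(x$ci_low[names(x$estimates)], 2)
    tab$ci_high <- round(x$ci_high[names(x$estimates)], 2)
  }
  print(tab, row.names = FALSE)
  if (!is.null(x$B)) cat(sprintf("bootstrap: B = %d, method = %s\n",
                                 x$B, x$details$ci_method %||% "?"))
  invisible(x)
}

outcome_values <- function(forest, outcome) {
  if (!outcome %in% names(forest))
    stop_rds(paste0("outcome column not found: ", outcome),
             "rds_validation_error")
  as.character(forest[[outcome]])
}

outcome_categories <- function(values) sort(unique(values[!is.na(values)]))

# ---- crude ----------------------------------------------------------------

est_core_crude <- function(values, denominator = c("all_records",
                                                   "non_missing")) {
  denominator <- match.arg(denominator)
  cats <- outcome_categories(values)
  den <- if (denominator == "all_records") length(values)
         else sum(!is.na(values))
  if (den == 0)
    stop_rds("no usable records for crude proportion", "rds_estimate_error")
  cnt <- vapply(cats, function(g) sum(values == g, na.rm = TRUE), numeric(1))
  stats::setNames(pct(cnt, den), cats)
}

#' Crude (unweighted) sample proportions of an outcome
#'
#' @param forest An [rds_forest()].
#' @param outcome Name of the outcome column.
#' @param denominator `"all_records"` (default) divides by the full sample
#'   size, so categories sum to less than 100% when non-response is
#'   present; `"non_missing"` divides by the responders only.
#' @return An `rds_estimate` with per-category percentages.
#' @export
crude_proportion <- function(forest, outcome,
                             denominator = c("all_records", "non_missing")) {
  stopifnot(inherits(forest, "rds_forest"))
  denominator <- match.arg(denominator)
  if (!nrow(forest))
    stop_rds("empty forest", "rds_estimate_error")
  values <- outcome_values(forest, outcome)
  est <- est_core_crude(values, denominator)
  n_used <- if (denominator == "all_records") length(values)
            else sum(!is.na(values))
  new_rds_estimate("crude", outcome, est, n_used = n_used,
                   details = list(denominator = denominator))
}

# ---- RDS-II ---------------------------------------------------------------

est_core_rds_ii <- function(values, degrees) {
  use <- !is.na(values)
  if (!any(use))
    stop_rds("no records with a non-missing outcome", "rds_estimate_error")
  w <- 1 / degrees[use]
  v <- values[use]
  cats <- outcome_categories(v)
  est <- vapply(cats, function(g) sum(w[v == g]) / sum(w), numeric(1))
  list(estimates = stats::setNames(100 * est, cats), weights = w,
       n_used = sum(use))
}

#' RDS-II (Volz-Heckathorn) inverse-degree estimator
#'
#' Weights each responder by the reciprocal of their reported network size,
#' the with-replacement random-walk approximation to their sampling
#' probability: for category A,
#' \eqn{\hat P_A = \sum_{i \in A} d_i^{-1} / \sum_{i \in S} d_i^{-1}}.
#' Records with a missing outcome are excluded (non-response).
#'
#' @inheritParams crude_proportion
#' @return An `rds_estimate`; `weights` holds the per-record \eqn{1/d_i}.
#' @export
rds_ii <- function(forest, outcome) {
  stopifnot(inherits(forest, "rds_forest"))
  values <- outcome_values(forest, outcome)
  core <- est_core_rds_ii(values, forest$degree)
  use <- !is.na(values)
  new_rds_estimate("rds_ii", outcome, core$estimates,
                   weights = stats::setNames(core$weights, forest$id[use]),
                   n_used = core$n_used)
}

# ---- successive sampling --------------------------------------------------

ss_depletion <- function(N_d, d, n) {
  m <- N_d
  for (k in seq_len(n)) {
    # Remove one unit of expected mass, degree-proportionally; if a class
    # would go negative (end-game of a near-census), empty it and
    # redistribute the excess so each draw removes exactly one unit.
    R <- 1
    repeat {
      tot <- sum(d * m)
      if (tot <= 0 || R <= 0) break
      r <- d * m / tot * R
      over <- m > 0 & r >= m
      if (!any(over)) {
        m <- m - r
        break
      }
      R <- R - sum(m[over])
      m[over] <- 0
    }
    if (sum(m) <= 0) break
  }
  (N_d - m) / N_d
}

#' Successive-sampling inclusion probabilities by degree
#'
#' Deterministic expected-depletion approximation to probability-
#' proportional-to-degree sampling without replacement: starting from the
#' estimated population count of each degree class, each of the `n` draws
#' removes mass from class `d` in proportion to `d` times its remaining
#' mass; the inclusion probability of degree `d` is the removed fraction of
#' its class. Probabilities are non-decreasing in degree and satisfy
#' \eqn{\sum_d \hat N_d \pi_d = n}.
#'
#' @param N_d Estimated population counts per degree class: a named numeric
#'   vector (names are the degrees) or a data.frame with columns `degree`
#'   and `N_hat`.
#' @param n Number of draws (sample size); must not exceed `sum(N_d)`.
#' @return A data.frame with columns `degree`, `N_hat` and `pi`, with
#'   attributes `iterations` (the number of depletion steps, `n`) and
#'   `converged`.
#' @export
ss_inclusion_probs <- function(N_d, n) {
  if (is.data.frame(N_d)) {
    d <- as.numeric(N_d$degree)
    Nv <- as.numeric(N_d$N_hat)
  } else {
    d <- as.numeric(names(N_d))
    Nv <- as.numeric(N_d)
  }
  if (anyNA(d) || any(d < 1))
    stop_rds("degrees must be numeric and >= 1", "rds_validation_error")
  if (n > sum(Nv))
    stop_rds("sample size n exceeds the population size", "rds_validation_error")
  o <- order(d)
  d <- d[o]; Nv <- Nv[o]
  pi_d <- ss_depletion(Nv, d, n)
  structure(data.frame(degree = d, N_hat = Nv, pi = pi_d),
            iterations = n, converged = TRUE)
}

est_core_rds_ss <- function(values, degrees, N, tol = 1e-6, max_iter = 50) {
  use <- !is.na(values)
  if (!any(use))
    stop_rds("no records with a non-missing outcome", "rds_estimate_error")
  v <- values[use]
  d <- degrees[use]
  n <- length(d)
  if (N < n)
    stop_rds("population size N smaller than the sample", "rds_validation_error")
  ud <- sort(unique(d))
  df <- factor(d, levels = ud)
  w <- 1 / d
  pi_prev <- NULL
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    share <- as.vector(rowsum(w, df))
    N_hat <- N * share / sum(share)
    pi_d <- ss_depletion(N_hat, ud, n)
    if (!is.null(pi_prev) && max(abs(pi_d - pi_prev)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    pi_prev <- pi_d
    w <- 1 / pi_d[as.integer(df)]
  }
  w <- 1 / pi_d[as.integer(df)]
  cats <- outcome_categories(v)
  est <- vapply(cats, function(g) sum(w[v == g]) / sum(w), numeric(1))
  list(estimates = stats::setNames(100 * est, cats), weights = w,
       n_used = n, converged = converged, iterations = iter,
       pi = stats::setNames(pi_d, ud), N_hat = stats::setNames(N_hat, ud))
}

#' RDS-SS successive-sampling estimator
#'
#' Accounts for the finite-population, without-replacement character of RDS
#' when the sample fraction is non-negligible. A fixed point is iterated:
#' starting from inverse-degree weights, the population count of each
#' degree class is estimated from the weighted degree distribution scaled
#' to the known population size `N`, inclusion probabilities are computed
#' by [ss_inclusion_probs()], and the weights are replaced by their
#' reciprocals, until the probabilities change by less than `tol`. As
#' \eqn{N \to \infty} the estimate converges to [rds_ii()]; at `N = n`
#' (a census) every inclusion probability is 1 and the estimate equals the
#' crude proportion among responders.
#'
#' @inheritParams crude_proportion
#' @param N Assumed population size.
#' @param tol Convergence tolerance on the maximum absolute change of the
#'   inclusion probabilities (default `1e-6`).
#' @param max_iter Iteration cap (default 50); on non-convergence the last
#'   iterate is returned with `details$converged = FALSE`.
#' @return An `rds_estimate`; `details` carries the inclusion-probability
#'   table, iteration count and convergence flag.
#' @export
rds_ss <- function(forest, outcome, N, tol = 1e-6, max_iter = 50) {
  stopifnot(inherits(forest, "rds_forest"))
  values <- outcome_values(forest, outcome)
  core <- est_core_rds_ss(values, forest$degree, N, tol, max_iter)
  use <- !is.na(values)
  if (!core$converged)
    warning("RDS-SS fixed point did not converge; returning last iterate")
  new_rds_estimate("rds_ss", outcome, core$estimates,
                   weights = stats::setNames(core$weights, forest$id[use]),
                   n_used = core$n_used,
                   details = list(N = N, pi = core$pi, N_hat = core$N_hat,
                                  converged = core$converged,
                                  iterations = core$iterations))
}
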