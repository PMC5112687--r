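# Recruitment Markov model: recruiter-to-recruit transition counts,
# equilibrium distribution, group harmonic-mean degrees and homophily,
# plus the Salganik-Heckathorn RDS-I estimator built on them.

row_normalize <- function(R) {
  rs <- rowSums(R)
  zero <- rs == 0
  T_ <- R
  T_[!zero, ] <- R[!zero, , drop = FALSE] / rs[!zero]
  # A group never observed recruiting gets an uninformative uniform row so
  # the chain remains stochastic; callers receive the flag.
  if (any(zero)) T_[zero, ] <- 1 / ncol(R)
  list(probs = T_, zero_rows = rownames(R)[zero])
}

stationary_dist <- function(T_, tol = 1e-12, max_iter = 1e5) {
  G <- nrow(T_)
  v <- rep(1 / G, G)
  for (i in seq_len(max_iter)) {
    v2 <- as.vector(v %*% T_)
    if (max(abs(v2 - v)) < tol) return(stats::setNames(v2, rownames(T_)))
    v <- v2
  }
  # Fallback for slowly mixing or periodic chains: left eigenvector of the
  # unit eigenvalue.
  ev <- eigen(t(T_))
  j <- which.min(abs(ev$values - 1))
  v <- abs(Re(ev$vectors[, j]))
  stats::setNames(v / sum(v), rownames(T_))
}

homophily_from <- function(T_, e) {
  G <- length(e)
  H <- stats::setNames(rep(NA_real_, G), names(e))
  for (g in seq_len(G)) {
    if (e[g] <= 0 || e[g] >= 1) next  # degenerate: index undefined
    H[g] <- if (T_[g, g] >= e[g]) (T_[g, g] - e[g]) / (1 - e[g])
            else (T_[g, g] - e[g]) / e[g]
  }
  H
}

transition_core <- function(from, to, groups, smoothed) {
  R <- table(factor(from, levels = groups), factor(to, levels = groups))
  R <- matrix(as.numeric(R), nrow = length(groups),
              dimnames = list(groups, groups))
  rn <- row_normalize(R)
  T_ <- rn$probs
  e <- stationary_dist(T_)
  flags <- list(zero_rows = rn$zero_rows, degenerate = FALSE)
  if (smoothed) {
    # Reciprocity ("data") smoothing: average each directed flow with its
    # reverse under the equilibrium, then re-normalize and re-solve.
    A <- e * T_
    S <- (A + t(A)) / 2
    rs <- rowSums(S)
    keep <- rs > 0
    if (any(!keep)) flags$zero_rows <- union(flags$zero_rows,
                                             groups[!keep])
    S[keep, ] <- S[keep, , drop = FALSE] / rs[keep]
    if (any(!keep)) S[!keep, ] <- 1 / length(groups)
    T_ <- S
    e <- stationary_dist(T_)
  }
  if (any(e <= 1e-12) || any(e >= 1 - 1e-12)) flags$degenerate <- TRUE
  list(counts = R, probs = T_, equilibrium = e,
       homophily = homophily_from(T_, e), flags = flags)
}

#' Recruiter-to-recruit transition model for an outcome
#'
#' Treats recruitment as a Markov chain on outcome groups: counts every
#' recruiter-recruit pair with both outcomes observed, row-normalizes the
#' count matrix into transition probabilities, and solves for the
#' equilibrium (stationary) group distribution. Optionally the counts are
#' reciprocity-smoothed — each directed flow is averaged with its reverse
#' under the equilibrium — before re-normalizing, which enforces the
#' balance assumed by the RDS-I estimator. Per-group harmonic-mean degrees
#' and homophily indices are computed alongside.
#'
#' @inheritParams crude_proportion
#' @param smoothed Apply reciprocity smoothing (default `TRUE`).
#' @return An object of class `rds_transition_model`: a list with
#'   `outcome`, `groups`, `counts`, `probs`, `equilibrium`,
#'   `harmonic_degrees`, `homophily`, `smoothed` and `flags` (groups with
#'   no observed recruitments; degenerate equilibrium).
#' @export
build_transition_model <- function(forest, outcome, smoothed = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  values <- outcome_values(forest, outcome)
  groups <- outcome_categories(values)
  if (length(groups) < 1)
    stop_rds("outcome has no observed categories", "rds_estimate_error")
  parent <- match(forest$recruiter_id, forest$id)
  has_pair <- !is.na(parent) & !is.na(values) & !is.na(values[parent])
  if (!any(has_pair))
    stop_rds("no recruiter-recruit pairs with both outcomes observed",
             "rds_estimate_error")
  from <- values[parent[has_pair]]
  to <- values[has_pair]
  core <- transition_core(from, to, groups, smoothed)
  if (length(core$flags$zero_rows))
    warning(sprintf(
      "group(s) never observed recruiting (%s); transition row set uniform",
      paste(core$flags$zero_rows, collapse = ", ")))
  hd <- vapply(groups, function(g) {
    dg <- forest$degree[!is.na(values) & values == g]
    if (!length(dg)) return(NA_real_)
    length(dg) / sum(1 / dg)
  }, numeric(1))
  structure(list(outcome = outcome, groups = groups, counts = core$counts,
                 probs = core$probs, equilibrium = core$equilibrium,
                 harmonic_degrees = hd, homophily = core$homophily,
                 smoothed = smoothed, n_pairs = length(to),
                 flags = core$flags),
            class = "rds_transition_model")
}

#' @export
print.rds_transition_model <- function(x, ...) {
  cat(sprintf("<rds_transition_model> outcome '%s' (%d pairs%s)\n",
              x$outcome, x$n_pairs,
              if (x$smoothed) ", smoothed" else ""))
  cat("transition probabilities:\n")
  print(round(x$probs, 3))
  cat("equilibrium:", paste(sprintf("%s=%.3f", x$groups, x$equilibrium),
                            collapse = ", "), "\n")
  cat("harmonic degrees:", paste(sprintf("%s=%.2f", x$groups,
                                         x$harmonic_degrees),
                                 collapse = ", "), "\n")
  cat("homophily:", paste(sprintf("%s=%.3f", x$groups, x$homophily),
                          collapse = ", "), "\n")
  invisible(x)
}

rds_i_from_model <- function(model) {
  e <- model$equilibrium
  D <- model$harmonic_degrees
  ok <- !is.na(D)
  score <- e[ok] / D[ok]
  stats::setNames(100 * score / sum(score), model$groups[ok])
}

# Two-group closed form, P_A = C_BA D_B / (C_AB D_A + C_BA D_B); used as an
# algebraic cross-check of the general equilibrium-based formula.
rds_i_two_group <- function(C_AB, C_BA, D_A, D_B) {
  pA <- C_BA * D_B / (C_AB * D_A + C_BA * D_B)
  100 * c(A = pA, B = 1 - pA)
}

#' RDS-I (Salganik-Heckathorn) estimator
#'
#' Combines the equilibrium group distribution of the recruitment Markov
#' chain with per-group harmonic-mean degrees: for group g,
#' \eqn{\hat P_g = (e_g / \hat D_g) / \sum_h (e_h / \hat D_h)}. For two
#' groups this reduces to the classical closed form
#' \eqn{\hat P_A = C_{BA}\hat D_B / (C_{AB}\hat D_A + C_{BA}\hat D_B)}
#' in the cross-recruitment probabilities.
#'
#' @inheritParams build_transition_model
#' @return An `rds_estimate`; `details` records the transition model used.
#' @export
rds_i <- function(forest, outcome, smoothed = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  model <- build_transition_model(forest, outcome, smoothed = smoothed)
  values <- outcome_values(forest, outcome)
  # A group with sampled members but no recruitment pairs has no footing in
  # the Markov model; its equilibrium share is an artefact of the uniform
  # fill-in, so estimation is refused rather than silently wrong.
  orphan <- model$groups[rowSums(model$counts) + colSums(model$counts) == 0]
  if (length(orphan))
    stop_rds(paste0(
      "group(s) absent from all recruitment pairs: ",
      paste(orphan, collapse = ", "),
      "; RDS-I is undefined for them. Collapse categories or use rds_ii()."),
      "rds_estimate_error")
  est <- rds_i_from_model(model)
  n_used <- sum(!is.na(values))
  new_rds_estimate("rds_i", outcome, est, n_used = n_used,
                   details = list(model = model, smoothed = smoothed))
}
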