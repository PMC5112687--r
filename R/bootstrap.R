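# Grouped chain bootstrap (Salganik-style) for RDS estimator variance.
# Replicates re-enact recruitment as a Markov chain on outcome groups:
# each replicate starts from an observed seed and repeatedly draws, with
# replacement, a successor from the pool of participants whose recruiter
# belongs to the current participant's group, until the replicate reaches
# the sample size. The estimator is recomputed on every replicate.

MISSING_GROUP <- ".missing"

# Simulate B replicate paths through the record table; returns an n x B
# integer matrix of record indices. Fully determined by the caller's RNG
# state. Missing outcomes form their own walk state so chains can pass
# through non-responders, while estimation still excludes them.
bootstrap_paths <- function(forest, outcome, B) {
  n <- nrow(forest)
  values <- outcome_values(forest, outcome)
  grp_lab <- ifelse(is.na(values), MISSING_GROUP, values)
  glev <- sort(unique(grp_lab))
  gidx <- match(grp_lab, glev)
  parent <- match(forest$recruiter_id, forest$id)
  child <- which(!is.na(parent))
  pools <- split(child, factor(grp_lab[parent[child]], levels = glev))
  sizes <- lengths(pools)
  seeds_idx <- which(is.na(parent))

  # Reachability of groups from the seed groups through the pools; an
  # empty pool for a reachable group would strand the walk.
  reach <- unique(gidx[seeds_idx])
  repeat {
    nxt <- unique(unlist(lapply(reach, function(g) {
      if (sizes[g] == 0) integer() else unique(gidx[pools[[g]]])
    })))
    new <- setdiff(nxt, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  stuck <- reach[sizes[reach] == 0]
  if (length(stuck))
    stop_rds(paste0("bootstrap pool empty for reachable group(s): ",
                    paste(glev[stuck], collapse = ", ")),
             "rds_bootstrap_error")

  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  pool_all <- unlist(pools, use.names = FALSE)
  P <- matrix(0L, nrow = n, ncol = B)
  start <- seeds_idx[sample.int(length(seeds_idx), B, replace = TRUE)]
  P[1, ] <- start
  state <- gidx[start]
  if (n > 1) for (t in 2:n) {
    u <- floor(stats::runif(B) * sizes[state]) + 1L
    u <- pmin.int(u, sizes[state])
    draw <- pool_all[offs[state] + u]
    P[t, ] <- draw
    state <- gidx[draw]
  }
  P
}

# Estimate matrix (B x categories) for the replicate paths. Consecutive
# draws play the role of recruiter-recruit pairs for RDS-I.
bootstrap_estimates <- function(forest, outcome, P, estimator, cats,
                                N = NULL, smoothed = TRUE,
                                denominator = "all_records",
                                tol = 1e-6, max_iter = 50) {
  values <- outcome_values(forest, outcome)
  degrees <- forest$degree
  B <- ncol(P)
  n <- nrow(P)
  if (estimator %in% c("crude", "rds_ii")) {
    V <- matrix(values[P], n, B)
    W <- if (estimator == "rds_ii") matrix(1 / degrees[P], n, B)
         else matrix(1, n, B)
    den <- if (estimator == "crude" && denominator == "all_records")
             rep(n, B)
           else colSums(W * !is.na(V))
    out <- sapply(cats, function(g)
      100 * colSums(W * (!is.na(V) & V == g)) / den)
    matrix(out, B, length(cats), dimnames = list(NULL, cats))
  } else {
    out <- matrix(NA_real_, B, length(cats),
                  dimnames = list(NULL, cats))
    for (b in seq_len(B)) {
      idx <- P[, b]
      v <- values[idx]
      d <- degrees[idx]
      est <- tryCatch({
        if (estimator == "rds_ss") {
          est_core_rds_ss(v, d, N, tol, max_iter)$estimates
        } else {
          ok <- !is.na(v)
          vv <- v[ok]; dd <- d[ok]
          grp <- sort(unique(vv))
          # pairs = consecutive responders in the replicate walk
          pr <- which(!is.na(v[-n]) & !is.na(v[-1]))
          if (!length(pr)) stop("no pairs")
          core <- transition_core(v[pr], v[pr + 1L], grp, smoothed)
          hd <- vapply(grp, function(g) {
            dg <- dd[vv == g]
            length(dg) / sum(1 / dg)
          }, numeric(1))
          score <- core$equilibrium / hd
          stats::setNames(100 * score / sum(score), grp)
        }
      }, error = function(e) NULL)
      if (!is.null(est)) {
        out[b, ] <- 0
        out[b, names(est)] <- est
      }
    }
    out
  }
}

#' Grouped chain-bootstrap confidence intervals for an RDS estimator
#'
#' @inheritParams crude_proportion
#' @param estimator One of `"rds_ii"`, `"rds_i"`, `"rds_ss"`, `"crude"`.
#' @param B Number of bootstrap replicates (default 1000).
#' @param seed Integer seed making the replicate stream reproducible;
#'   `NULL` uses the current RNG state.
#' @param method `"normal"` (point estimate ± 1.96 bootstrap SD, the
#'   default) or `"percentile"` (2.5/97.5 replicate percentiles).
#' @param N Population size, required for `estimator = "rds_ss"`.
#' @param smoothed Passed to the RDS-I transition model.
#' @param denominator Passed to [crude_proportion()].
#' @param keep_replicates Keep the B x category replicate estimate matrix
#'   in `details$replicates` (default `TRUE`).
#' @return An `rds_estimate` with `ci_low`/`ci_high` filled per category
#'   and the bootstrap SE in `details$se`.
#' @export
bootstrap_ci <- function(forest, outcome,
                         estimator = c("rds_ii", "rds_i", "rds_ss", "crude"),
                         B = 1000, seed = NULL,
                         method = c("normal", "percentile"), N = NULL,
                         smoothed = TRUE, denominator = "all_records",
                         keep_replicates = TRUE) {
  stopifnot(inherits(forest, "rds_forest"), B >= 2)
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  if (estimator == "rds_ss" && is.null(N))
    stop_rds("rds_ss bootstrap requires the population size N",
             "rds_validation_error")
  point <- estimate_forest(forest, outcome, estimator, N = N,
                           smoothed = smoothed, denominator = denominator)
  cats <- names(point$estimates)
  reps <- with_rng_seed(seed, {
    P <- bootstrap_paths(forest, outcome, B)
    bootstrap_estimates(forest, outcome, P, estimator, cats, N = N,
                        smoothed = smoothed, denominator = denominator)
  })
  failed <- rowSums(is.na(reps)) > 0
  if (any(failed))
    warning(sprintf("%d bootstrap replicate(s) failed and were dropped",
                    sum(failed)))
  reps_ok <- reps[!failed, , drop = FALSE]
  se <- apply(reps_ok, 2, stats::sd)
  if (method == "normal") {
    lo <- point$estimates - 1.96 * se
    hi <- point$estimates + 1.96 * se
  } else {
    qs <- apply(reps_ok, 2, stats::quantile, probs = c(0.025, 0.975))
    lo <- qs[1, ]
    hi <- qs[2, ]
  }
  point$ci_low <- stats::setNames(pmax(as.numeric(lo), 0), cats)
  point$ci_high <- stats::setNames(pmin(as.numeric(hi), 100), cats)
  point$B <- as.integer(B)
  point$seed <- seed
  point$details$se <- stats::setNames(as.numeric(se), cats)
  point$details$ci_method <- method
  point$details$failed_replicates <- sum(failed)
  if (keep_replicates) point$details$replicates <- reps_ok
  point
}

# Single dispatch point used by bootstrap, diagnostics and sensitivity.
estimate_forest <- function(forest, outcome, estimator, N = NULL,
                            smoothed = TRUE, denominator = "all_records",
                            tol = 1e-6, max_iter = 50) {
  switch(estimator,
    crude = crude_proportion(forest, outcome, denominator = denominator),
    rds_i = rds_i(forest, outcome, smoothed = smoothed),
    rds_ii = rds_ii(forest, outcome),
    rds_ss = {
      if (is.null(N))
        stop_rds("rds_ss requires the population size N",
                 "rds_validation_error")
      rds_ss(forest, outcome, N = N, tol = tol, max_iter = max_iter)
    },
    stop_rds(paste0("unknown estimator: ", estimator),
             "rds_validation_error"))
}
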