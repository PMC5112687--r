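# Graphical and analytic diagnostics: convergence series (running estimate
# versus number of recruits), per-seed bottleneck series, homophily
# indices and the analytic waves-to-equilibrium computation.

new_diag_series <- function(df, outcome, estimator, category, seed_id = NA,
                            skipped = integer(), final = NA_real_) {
  structure(df, outcome = outcome, estimator = estimator,
            category = category, seed_id = seed_id, skipped = skipped,
            final = final, class = c("rds_diag_series", "data.frame"))
}

# Enrollment ordering: explicit enroll_order when available, otherwise
# breadth-first by wave with stable id order.
series_order <- function(forest) {
  eo <- forest$enroll_order
  if (!is.null(eo) && !anyNA(eo)) order(eo)
  else order(forest$wave, forest$id)
}

series_values <- function(forest, ord, outcome, estimator, category, k_min,
                          N = NULL, smoothed = TRUE) {
  n <- length(ord)
  values <- outcome_values(forest, outcome)[ord]
  degrees <- forest$degree[ord]
  ks <- seq.int(k_min, n)
  if (estimator %in% c("crude", "rds_ii")) {
    w <- if (estimator == "rds_ii") 1 / degrees else rep(1, n)
    wnum <- cumsum(ifelse(!is.na(values) & values == category, w, 0))
    wden <- if (estimator == "crude") seq_len(n)
            else cumsum(ifelse(!is.na(values), w, 0))
    vals <- 100 * wnum[ks] / wden[ks]
    skipped <- ks[!is.finite(vals)]
    return(list(k = ks[is.finite(vals)], value = vals[is.finite(vals)],
                skipped = skipped))
  }
  # General path: re-estimate on each prefix, treating records whose
  # recruiter falls outside the prefix as seeds.
  ids <- forest$id[ord]
  recs <- as.data.frame(forest)[ord, , drop = FALSE]
  out_k <- numeric(0)
  out_v <- numeric(0)
  skipped <- integer(0)
  for (k in ks) {
    sub <- recs[seq_len(k), , drop = FALSE]
    sub$recruiter_id[!(sub$recruiter_id %in% sub$id)] <- NA
    val <- tryCatch({
      f <- rds_forest(sub, outcomes = attr(forest, "outcomes"))
      est <- estimate_forest(f, outcome, estimator, N = N,
                             smoothed = smoothed)
      unname(est$estimates[category])
    }, error = function(e) NA_real_)
    if (is.na(val)) skipped <- c(skipped, k)
    else {
      out_k <- c(out_k, k)
      out_v <- c(out_v, val)
    }
  }
  list(k = out_k, value = out_v, skipped = skipped)
}

#' Convergence series of a running estimate
#'
#' Recomputes the chosen estimator on the first k enrolled participants for
#' k from `k_min` to n, in enrollment order. Stabilization of the series
#' (a flat right-hand tail) suggests the estimate has escaped the influence
#' of the purposively chosen seeds; plotted, this is the standard RDS
#' convergence plot.
#'
#' @inheritParams crude_proportion
#' @param estimator Estimator recomputed at each prefix (default
#'   `"rds_ii"`, which is stable on short prefixes).
#' @param category Outcome category whose percentage is tracked; default
#'   the first category in sorted order.
#' @param k_min First prefix size (default 10; earlier prefixes are too
#'   unstable to be informative).
#' @param N Population size, needed when `estimator = "rds_ss"`.
#' @param smoothed Passed to the RDS-I transition model.
#' @return An `rds_diag_series` data.frame with columns `k` and `value`;
#'   prefixes where the estimator is undefined are skipped and recorded in
#'   `attr(, "skipped")`. The final point equals the full-sample estimate.
#' @export
convergence_series <- function(forest, outcome, estimator = "rds_ii",
                               category = NULL, k_min = 10, N = NULL,
                               smoothed = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  if (nrow(forest) < k_min)
    stop_rds(sprintf("need at least k_min = %d usable records", k_min),
             "rds_estimate_error")
  values <- outcome_values(forest, outcome)
  category <- category %||% outcome_categories(values)[1]
  ord <- series_order(forest)
  sv <- series_values(forest, ord, outcome, estimator, category, k_min,
                      N = N, smoothed = smoothed)
  new_diag_series(data.frame(k = sv$k, value = sv$value),
                  outcome, estimator, category,
                  skipped = sv$skipped,
                  final = sv$value[length(sv$value)])
}

#' Per-seed bottleneck series
#'
#' One convergence series per recruitment chain, each computed over that
#' chain's members only. Superimposed, these are the bottleneck plot: all
#' chains converging on a common value indicates low homophily (one
#' "bottleneck"), while chains stabilizing at distinct values indicate
#' homophily-driven segregation (two or more bottlenecks).
#'
#' @inheritParams convergence_series
#' @param k_min Minimum chain size for a series (default 10); smaller
#'   chains are skipped and listed in `attr(, "skipped_chains")`.
#' @return A list of `rds_diag_series` (one per retained chain, named by
#'   seed id) of class `rds_bottleneck_set`.
#' @export
bottleneck_series <- function(forest, outcome, estimator = "rds_ii",
                              category = NULL, k_min = 10, N = NULL,
                              smoothed = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  values <- outcome_values(forest, outcome)
  category <- category %||% outcome_categories(values)[1]
  seeds <- unique(forest$seed_id)
  out <- list()
  skipped <- character(0)
  for (s in seeds) {
    rows <- which(forest$seed_id == s)
    if (length(rows) < k_min) {
      skipped <- c(skipped, s)
      next
    }
    sub <- new_rds_forest(as.data.frame(forest)[rows, , drop = FALSE],
                          attr(forest, "outcomes"))
    ord <- series_order(sub)
    sv <- series_values(sub, ord, outcome, estimator, category, k_min,
                        N = N, smoothed = smoothed)
    out[[s]] <- new_diag_series(data.frame(k = sv$k, value = sv$value),
                                outcome, estimator, category, seed_id = s,
                                skipped = sv$skipped,
                                final = sv$value[length(sv$value)])
  }
  if (length(skipped))
    message(sprintf("skipped %d chain(s) below k_min = %d members",
                    length(skipped), k_min))
  structure(out, skipped_chains = skipped, outcome = outcome,
            estimator = estimator, category = category,
            class = "rds_bottleneck_set")
}

#' Tidy data.frame of one or more diagnostic series
#'
#' @param x An `rds_diag_series` or `rds_bottleneck_set`.
#' @return A data.frame with columns `outcome`, `estimator`, `category`,
#'   `seed_id`, `k`, `value`, ready for CSV export or plotting.
#' @export
series_table <- function(x) {
  one <- function(s)
    data.frame(outcome = attr(s, "outcome"), estimator = attr(s, "estimator"),
               category = attr(s, "category"),
               seed_id = as.character(attr(s, "seed_id")),
               k = s$k, value = s$value, stringsAsFactors = FALSE)
  if (inherits(x, "rds_diag_series")) return(one(x))
  if (inherits(x, "rds_bottleneck_set"))
    return(do.call(rbind, lapply(unclass(x), one)))
  stop_rds("not a diagnostic series", "rds_validation_error")
}

#' @export
plot.rds_diag_series <- function(x, ...) {
  plot(x$k, x$value, type = "l", xlab = "number of recruits",
       ylab = sprintf("%% %s (%s)", attr(x, "category"),
                      attr(x, "estimator")),
       main = sprintf("Convergence: %s", attr(x, "outcome")), ...)
  graphics::abline(h = attr(x, "final"), lty = 2, col = "grey50")
  invisible(x)
}

#' @export
plot.rds_bottleneck_set <- function(x, ...) {
  xs <- unclass(x)
  rng_k <- range(unlist(lapply(xs, function(s) s$k)))
  plot(NA, xlim = rng_k, ylim = c(0, 100), xlab = "number of recruits",
       ylab = sprintf("%% %s (%s)", attr(x, "category"),
                      attr(x, "estimator")),
       main = sprintf("Bottleneck: %s", attr(x, "outcome")), ...)
  for (i in seq_along(xs))
    graphics::lines(xs[[i]]$k, xs[[i]]$value, col = i)
  invisible(x)
}

#' Per-group homophily indices of a transition model
#'
#' Heckathorn-style index comparing a group's self-recruitment probability
#' with its equilibrium share: positive when members recruit within their
#' group more than the equilibrium predicts (up to +1 for complete
#' segregation), negative for avoidance (down to -1), 0 when recruitment is
#' proportionate.
#'
#' @param model An [build_transition_model()] result.
#' @return Named numeric vector of indices in \[-1, 1\]; `NA` for groups
#'   with a degenerate equilibrium share (0 or 1).
#' @export
homophily_index <- function(model) {
  stopifnot(inherits(model, "rds_transition_model"))
  model$homophily
}

#' Seed group distribution of a forest
#'
#' @inheritParams crude_proportion
#' @return Named probability vector over the outcome's categories among
#'   seeds with a non-missing outcome.
#' @export
seed_distribution <- function(forest, outcome) {
  stopifnot(inherits(forest, "rds_forest"))
  v <- outcome_values(forest, outcome)[forest$wave == 0L]
  v <- v[!is.na(v)]
  if (!length(v))
    stop_rds("no seeds with a non-missing outcome", "rds_estimate_error")
  tab <- table(factor(v, levels = outcome_categories(v)))
  as.vector(tab / sum(tab)) -> p
  stats::setNames(p, names(tab))
}

#' Waves needed for the recruitment chain to reach equilibrium
#'
#' Number of recruitment waves (Markov transitions) after which a starting
#' group distribution lies within `epsilon` of the equilibrium, in maximum
#' absolute component difference. The worst-case mode maximizes over all
#' degenerate starts (all seeds in a single group); the observed mode
#' starts from the empirical seed distribution.
#'
#' @param model An [build_transition_model()] result.
#' @param epsilon Convergence tolerance (default 0.01).
#' @param start `"worst_case"` (default), `"observed"` (requires `forest`),
#'   or a numeric start distribution over the model's groups.
#' @param forest Forest supplying the observed seed distribution.
#' @param max_waves Iteration cap; a chain still outside `epsilon` after
#'   this many waves (non-ergodic or near-periodic) reports `Inf` with a
#'   diagnosis.
#' @return An object of class `rds_equilibrium_report`: list with
#'   `epsilon`, `start_mode`, `waves` (per start), `waves_max`, the
#'   distance metric name and a `diagnosis` string when degenerate.
#' @export
equilibrium_waves <- function(model, epsilon = 0.01,
                              start = "worst_case", forest = NULL,
                              max_waves = 10000) {
  stopifnot(inherits(model, "rds_transition_model"), epsilon > 0)
  T_ <- model$probs
  e <- model$equilibrium
  G <- length(e)
  if (is.numeric(start)) {
    starts <- list(custom = start / sum(start))
    mode <- "custom"
  } else if (identical(start, "worst_case")) {
    starts <- lapply(seq_len(G), function(g) {
      v <- numeric(G); v[g] <- 1; v
    })
    names(starts) <- model$groups
    mode <- "worst_case"
  } else if (identical(start, "observed")) {
    if (is.null(forest))
      stop_rds("start = 'observed' requires the forest", "rds_validation_error")
    sd_ <- seed_distribution(forest, model$outcome)
    v <- numeric(G)
    v[match(names(sd_), model$groups)] <- sd_
    starts <- list(observed = v)
    mode <- "observed"
  } else stop_rds("unknown start mode", "rds_validation_error")

  waves <- vapply(starts, function(v) {
    w <- 0L
    repeat {
      if (max(abs(v - e)) < epsilon) return(as.numeric(w))
      if (w >= max_waves) return(Inf)
      v <- as.vector(v %*% T_)
      w <- w + 1L
    }
  }, numeric(1))
  diagnosis <- if (any(!is.finite(waves)))
    "chain did not reach equilibrium within max_waves; transition matrix may be reducible or periodic"
  else NA_character_
  structure(list(epsilon = epsilon, start_mode = mode, waves = waves,
                 waves_max = max(waves), distance = "max_abs",
                 equilibrium = e, diagnosis = diagnosis),
            class = "rds_equilibrium_report")
}

#' @export
print.rds_equilibrium_report <- function(x, ...) {
  cat(sprintf(
    "<rds_equilibrium_report> eps = %g (%s start): %s wave(s) to equilibrium\n",
    x$epsilon, x$start_mode, format(x$waves_max)))
  if (length(x$waves) > 1)
    cat("per start:", paste(sprintf("%s=%s", names(x$waves),
                                    format(x$waves)), collapse = ", "), "\n")
  if (!is.na(x$diagnosis)) cat("note:", x$diagnosis, "\n")
  invisible(x)
}
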