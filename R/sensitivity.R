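# Seed-sensitivity experiments: (i) stepwise seed-exclusion re-estimation
# across sample cuts with crude-within-CI containment checks; (ii) the
# seed-tree subsampling comparison of estimators.

cut_label <- function(c) if (is.na(c)) "overall" else paste0(">", c)

#' Re-estimate outcomes across seed-productivity sample cuts
#'
#' For the overall sample and each cut (removing chains of depth at most
#' c), recomputes crude proportions and the requested RDS-weighted
#' estimators with grouped chain-bootstrap confidence intervals, and checks
#' whether each crude proportion falls inside each weighted estimator's CI
#' — the robustness-to-seed-selection criterion.
#'
#' @param forest An [rds_forest()].
#' @param outcomes Character vector of outcome columns (default: all).
#' @param estimators Weighted estimators to run (default RDS-I, RDS-II,
#'   RDS-SS).
#' @param N Population size; required when `"rds_ss"` is requested.
#' @param B Bootstrap replicates per estimate (default 1000).
#' @param seed Master seed; each (cut, outcome, estimator) cell gets a
#'   derived sub-seed so cells are individually reproducible.
#' @param cuts Minimum-depth cuts (default `c(0, 1, 2)`).
#' @param denominator Denominator mode for the crude estimator.
#' @param smoothed Passed to the RDS-I transition model.
#' @param ci_method Bootstrap CI method, `"normal"` or `"percentile"`.
#' @return An object of class `rds_sensitivity`: list with `cut_summary`
#'   (the [cut_report()] table), `estimates` (tidy data.frame keyed by cut,
#'   outcome, category, estimator), `crude` (crude rows in the same shape),
#'   `containment` (logical per cut/outcome/estimator/category) and the
#'   run configuration.
#' @export
run_cut_analysis <- function(forest, outcomes = attr(forest, "outcomes"),
                             estimators = c("rds_i", "rds_ii", "rds_ss"),
                             N = NULL, B = 1000, seed = 1,
                             cuts = c(0, 1, 2),
                             denominator = "all_records", smoothed = TRUE,
                             ci_method = "normal") {
  stopifnot(inherits(forest, "rds_forest"))
  if ("rds_ss" %in% estimators && is.null(N))
    stop_rds("estimator rds_ss requested but N not supplied",
             "rds_validation_error")
  forests <- c(list(forest), lapply(cuts, prune_by_min_depth,
                                    forest = forest))
  names(forests) <- c("overall", paste0(">", cuts))
  cut_summary <- cut_report(forest, cuts = cuts)

  est_rows <- list()
  crude_rows <- list()
  notes <- character(0)
  cell <- 0L
  for (ci in seq_along(forests)) {
    f <- forests[[ci]]
    lab <- names(forests)[ci]
    if (!nrow(f)) {
      notes <- c(notes, sprintf("cut %s left zero records; skipped", lab))
      next
    }
    for (oc in outcomes) {
      cr <- tryCatch(crude_proportion(f, oc, denominator = denominator),
                     error = function(e) NULL)
      if (is.null(cr)) {
        notes <- c(notes, sprintf("crude undefined for %s / %s", lab, oc))
        next
      }
      crude_rows[[length(crude_rows) + 1L]] <- data.frame(
        cut = lab, outcome = oc, category = names(cr$estimates),
        estimator = "crude", n_used = cr$n_used,
        estimate = unname(cr$estimates), ci_low = NA_real_,
        ci_high = NA_real_, stringsAsFactors = FALSE)
      for (es in estimators) {
        cell <- cell + 1L
        res <- tryCatch(
          bootstrap_ci(f, oc, estimator = es, B = B,
                       seed = derive_seed(seed, cell), method = ci_method,
                       N = N, smoothed = smoothed,
                       keep_replicates = FALSE),
          error = function(e) {
            notes <<- c(notes, sprintf("%s failed for %s / %s: %s",
                                       es, lab, oc, conditionMessage(e)))
            NULL
          })
        if (is.null(res)) next
        est_rows[[length(est_rows) + 1L]] <- data.frame(
          cut = lab, outcome = oc, category = names(res$estimates),
          estimator = es, n_used = res$n_used,
          estimate = unname(res$estimates),
          ci_low = unname(res$ci_low[names(res$estimates)]),
          ci_high = unname(res$ci_high[names(res$estimates)]),
          stringsAsFactors = FALSE)
      }
    }
  }
  estimates <- do.call(rbind, est_rows)
  crude <- do.call(rbind, crude_rows)
  report <- structure(list(cut_summary = cut_summary, estimates = estimates,
                           crude = crude, notes = notes,
                           config = list(outcomes = outcomes,
                                         estimators = estimators, N = N,
                                         B = B, seed = seed, cuts = cuts,
                                         denominator = denominator,
                                         smoothed = smoothed,
                                         ci_method = ci_method)),
                      class = "rds_sensitivity")
  report$containment <- check_crude_within_cis(report)
  report
}

#' Crude-within-CI containment table
#'
#' Recomputes, for every (cut, outcome, estimator, category) cell of a
#' sensitivity report, whether the crude proportion lies inside the
#' weighted estimator's bootstrap confidence interval.
#'
#' @param report An [run_cut_analysis()] result.
#' @return A data.frame with the keys plus `crude`, `ci_low`, `ci_high`
#'   and logical `within`.
#' @export
check_crude_within_cis <- function(report) {
  stopifnot(inherits(report, "rds_sensitivity"))
  est <- report$estimates
  cr <- report$crude
  if (is.null(est) || is.null(cr)) return(NULL)
  key <- paste(cr$cut, cr$outcome, cr$category, sep = "\r")
  crude_of <- stats::setNames(cr$estimate, key)
  ekey <- paste(est$cut, est$outcome, est$category, sep = "\r")
  out <- data.frame(cut = est$cut, outcome = est$outcome,
                    category = est$category, estimator = est$estimator,
                    crude = unname(crude_of[ekey]),
                    ci_low = est$ci_low, ci_high = est$ci_high,
                    stringsAsFactors = FALSE)
  out$within <- out$crude >= out$ci_low & out$crude <= out$ci_high
  out
}

#' @export
print.rds_sensitivity <- function(x, ...) {
  cat("<rds_sensitivity>\n")
  print(x$cut_summary, row.names = FALSE)
  if (!is.null(x$containment)) {
    bad <- x$containment[!x$containment$within, , drop = FALSE]
    cat(sprintf("crude-within-CI: %d of %d cells contained\n",
                sum(x$containment$within), nrow(x$containment)))
    if (nrow(bad)) print(bad, row.names = FALSE)
  }
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' Seed-tree subsampling comparison of RDS estimators
#'
#' Repeatedly draws a random subset of whole recruitment chains (seed
#' trees), recomputes every estimator on the subsample, and summarizes the
#' replicate distribution of each estimator and of every pairwise
#' difference. The paired two-sided t-test p-value on the replicate
#' differences is descriptive: replicates share chains and are not
#' independent, so the percentile interval of the differences is reported
#' alongside.
#'
#' @inheritParams run_cut_analysis
#' @param estimators Estimators to compare (default crude, RDS-I, RDS-II,
#'   RDS-SS).
#' @param replicates Number of subsamples (default 100).
#' @param tree_fraction Fraction of chains drawn per replicate, without
#'   replacement within a replicate (default 0.5).
#' @param alpha Significance level recorded with the comparison
#'   (default 0.05).
#' @param categories Named character vector choosing, per outcome, the
#'   category whose percentage is compared; default the first category of
#'   each outcome in sorted order.
#' @param max_redraws A replicate on which some estimator is undefined is
#'   redrawn up to this many times (default 10) before erroring.
#' @return An object of class `rds_comparison`: list with `replicates`
#'   (the replicate x outcome x estimator array), `summary` (mean and
#'   2.5/97.5 percentiles per outcome and estimator), `pairwise` (mean
#'   difference, percentile interval and p-value per estimator pair and
#'   outcome, sign convention `first - second`) and the configuration.
#' @export
compare_estimators_simulation <- function(forest,
                                          outcomes = attr(forest, "outcomes"),
                                          estimators = c("crude", "rds_i",
                                                         "rds_ii", "rds_ss"),
                                          replicates = 100,
                                          tree_fraction = 0.5, alpha = 0.05,
                                          seed = 1, N = NULL,
                                          categories = NULL,
                                          denominator = "all_records",
                                          smoothed = TRUE,
                                          max_redraws = 10) {
  stopifnot(inherits(forest, "rds_forest"), replicates >= 2,
            tree_fraction > 0, tree_fraction <= 1)
  if ("rds_ss" %in% estimators && is.null(N))
    stop_rds("estimator rds_ss requested but N not supplied",
             "rds_validation_error")
  chains <- unique(forest$seed_id)
  if (length(chains) < 2)
    stop_rds("need at least two chains to subsample", "rds_validation_error")
  if (is.null(categories)) {
    categories <- vapply(outcomes, function(oc)
      outcome_categories(outcome_values(forest, oc))[1], character(1))
  }
  k <- ceiling(tree_fraction * length(chains))
  arr <- array(NA_real_, dim = c(replicates, length(outcomes),
                                 length(estimators)),
               dimnames = list(NULL, outcomes, estimators))
  redraw_log <- integer(replicates)
  with_rng_seed(seed, {
    for (r in seq_len(replicates)) {
      attempt <- 0L
      repeat {
        attempt <- attempt + 1L
        take <- sample(chains, k)
        sub <- new_rds_forest(
          as.data.frame(forest)[forest$seed_id %in% take, , drop = FALSE],
          attr(forest, "outcomes"))
        vals <- tryCatch({
          sapply(estimators, function(es) vapply(outcomes, function(oc) {
            est <- estimate_forest(sub, oc, es, N = N, smoothed = smoothed,
                                   denominator = denominator)
            unname(est$estimates[categories[[oc]]])
          }, numeric(1)))
        }, error = function(e) NULL)
        if (!is.null(vals) && !anyNA(vals)) break
        if (attempt > max_redraws)
          stop_rds(sprintf(
            "replicate %d: estimator undefined after %d redraws",
            r, max_redraws), "rds_estimate_error")
      }
      redraw_log[r] <- attempt - 1L
      arr[r, , ] <- matrix(vals, length(outcomes), length(estimators))
    }
  })

  summarize <- function(v) c(mean = mean(v),
                             q2.5 = unname(stats::quantile(v, 0.025)),
                             q97.5 = unname(stats::quantile(v, 0.975)))
  summ <- do.call(rbind, lapply(outcomes, function(oc)
    do.call(rbind, lapply(estimators, function(es) {
      s <- summarize(arr[, oc, es])
      data.frame(outcome = oc, estimator = es, mean = s["mean"],
                 q2.5 = s["q2.5"], q97.5 = s["q97.5"],
                 stringsAsFactors = FALSE, row.names = NULL)
    }))))

  pairs <- utils::combn(estimators, 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(outcomes, function(oc)
    do.call(rbind, lapply(pairs, function(p) {
      d <- arr[, oc, p[1]] - arr[, oc, p[2]]
      degen <- stats::sd(d) < .Machine$double.eps^0.5
      pval <- if (degen) NA_real_
              else stats::t.test(d)$p.value
      s <- summarize(d)
      data.frame(outcome = oc, pair = paste(p[1], "-", p[2]),
                 mean_diff = s["mean"], q2.5 = s["q2.5"], q97.5 = s["q97.5"],
                 p_value = pval, degenerate = degen,
                 significant = !degen && pval < alpha,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))))

  structure(list(replicates = arr, summary = summ, pairwise = pw,
                 redraws = redraw_log,
                 config = list(outcomes = outcomes, estimators = estimators,
                               categories = categories,
                               n_replicates = replicates,
                               tree_fraction = tree_fraction, alpha = alpha,
                               seed = seed, N = N)),
            class = "rds_comparison")
}

#' @export
print.rds_comparison <- function(x, ...) {
  cat(sprintf(
    "<rds_comparison> %d replicates, tree_fraction = %g, alpha = %g\n",
    x$config$n_replicates, x$config$tree_fraction, x$config$alpha))
  cat("estimator summaries:\n")
  print(transform(x$summary, mean = round(mean, 2), q2.5 = round(q2.5, 2),
                  q97.5 = round(q97.5, 2)), row.names = FALSE)
  cat("pairwise differences:\n")
  print(transform(x$pairwise, mean_diff = round(mean_diff, 2),
                  q2.5 = round(q2.5, 2), q97.5 = round(q97.5, 2),
                  p_value = round(p_value, 3)), row.names = FALSE)
  invisible(x)
}
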