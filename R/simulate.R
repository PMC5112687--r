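# Synthetic group-structured populations and coupon-based RDS recruitment
# with known ground truth. The generator emulates the design of a large
# urban GBMSM biobehavioural survey: ~34,000 eligible individuals, three
# binary outcomes with prevalences near 27% / 37% / 8%, heavy-tailed
# self-reported network sizes, a tunable group-mixing (homophily) matrix,
# up to 6 coupons per enrollee and seed top-ups whenever recruitment dies
# out before the target sample size.

default_outcomes <- function() {
  list(hiv = c(positive = 0.27, negative = 0.73),
       high_risk_sex = c(yes = 0.37, no = 0.63),
       idu = c(yes = 0.08, no = 0.92))
}

mixing_matrix <- function(mixing, G, groups) {
  if (is.matrix(mixing)) {
    M <- mixing
  } else {
    stopifnot(length(mixing) == 1, mixing > 0, mixing < 1)
    M <- matrix((1 - mixing) / max(G - 1, 1), G, G)
    diag(M) <- if (G > 1) mixing else 1
  }
  dimnames(M) <- list(groups, groups)
  if (any(abs(rowSums(M) - 1) > 1e-8))
    stop_rds("mixing matrix rows must sum to 1", "rds_validation_error")
  M
}

#' Generate a group-structured network population
#'
#' Builds an explicit simple graph over `N` individuals by degree-
#' respecting stub pairing steered by a mixing matrix: each individual
#' receives a target degree from a shifted negative-binomial distribution
#' (minimum 1, the heavy right tail typical of self-reported network
#' sizes), each of their stubs samples a partner group from the mixing
#' matrix row of their own group, and stubs are matched between and within
#' groups; unmatched stubs are paired uniformly and self-loops and
#' duplicate edges are dropped. One outcome (the `mixing_outcome`)
#' structures the network; the remaining outcomes are assigned
#' independently of it, so they carry essentially no homophily.
#'
#' @param N Population size (default 33960).
#' @param outcomes Named list of per-outcome category prevalence vectors
#'   (each summing to 1). Default: three binary outcomes with prevalences
#'   0.27, 0.37 and 0.08.
#' @param mixing Either a square row-stochastic matrix over the categories
#'   of `mixing_outcome`, or a scalar diagonal value (off-diagonal mass
#'   split evenly). Default 0.55, a mildly homophilous network.
#' @param mixing_outcome Which outcome structures the network ties
#'   (default the first).
#' @param degree_mean,degree_dispersion Mean and negative-binomial `size`
#'   of the target degree distribution before the +1 shift
#'   (defaults 20 and 1.5).
#' @param seed RNG seed.
#' @return An object of class `rds_population`: list with `N`, `nodes`
#'   (id, realized degree, outcome columns), `edges` (two-column integer
#'   matrix) and `truth` (a [truth_report()]).
#' @export
sim_population <- function(N = 33960, outcomes = default_outcomes(),
                           mixing = 0.55,
                           mixing_outcome = names(outcomes)[1],
                           degree_mean = 20, degree_dispersion = 1.5,
                           seed = NULL) {
  stopifnot(N >= 2, degree_mean > 1)
  for (oc in names(outcomes))
    if (abs(sum(outcomes[[oc]]) - 1) > 1e-8)
      stop_rds(sprintf("prevalences for outcome '%s' must sum to 1", oc),
               "rds_validation_error")
  with_rng_seed(seed, {
    nodes <- data.frame(id = seq_len(N))
    for (oc in names(outcomes)) {
      p <- outcomes[[oc]]
      nodes[[oc]] <- sample(names(p), N, replace = TRUE, prob = p)
    }
    groups <- sort(names(outcomes[[mixing_outcome]]))
    G <- length(groups)
    M <- mixing_matrix(mixing, G, groups)
    gidx <- match(nodes[[mixing_outcome]], groups)

    target_deg <- stats::rnbinom(N, size = degree_dispersion,
                                 mu = degree_mean - 1) + 1L
    owner <- rep.int(seq_len(N), target_deg)
    sg <- gidx[owner]
    # Each stub draws the group its tie should attach to.
    tg <- integer(length(owner))
    for (g in seq_len(G)) {
      idx <- which(sg == g)
      tg[idx] <- sample.int(G, length(idx), replace = TRUE, prob = M[g, ])
    }
    a <- integer(0); b <- integer(0)
    unmatched <- integer(0)
    for (g in seq_len(G)) {
      within <- which(sg == g & tg == g)
      within <- within[sample.int(length(within))]
      h <- length(within) %/% 2
      if (h) {
        a <- c(a, within[seq_len(h)])
        b <- c(b, within[h + seq_len(h)])
      }
      if (length(within) %% 2) unmatched <- c(unmatched, within[2 * h + 1])
      for (g2 in seq_len(G)) {
        if (g2 <= g) next
        fwd <- which(sg == g & tg == g2)
        bck <- which(sg == g2 & tg == g)
        k <- min(length(fwd), length(bck))
        if (k) {
          a <- c(a, fwd[sample.int(length(fwd), k)])
          b <- c(b, bck[sample.int(length(bck), k)])
        }
        unmatched <- c(unmatched,
                       if (length(fwd) > k) setdiff(fwd, a) else integer(),
                       if (length(bck) > k) setdiff(bck, b) else integer())
      }
    }
    # Leftover stubs (mixing-matrix flow imbalance) pair uniformly; this
    # dilutes the target mixing slightly but preserves degrees.
    unmatched <- unmatched[sample.int(length(unmatched))]
    h <- length(unmatched) %/% 2
    if (h) {
      a <- c(a, unmatched[seq_len(h)])
      b <- c(b, unmatched[h + seq_len(h)])
    }
    ea <- owner[a]; eb <- owner[b]
    keep <- ea != eb
    lo <- pmin.int(ea, eb)[keep]; hi <- pmax.int(ea, eb)[keep]
    dup <- duplicated(lo * (N + 1) + hi)
    edges <- cbind(lo[!dup], hi[!dup])

    realized <- tabulate(c(edges[, 1], edges[, 2]), N)
    nodes$degree <- pmax(realized, 1L)
    pop <- structure(list(N = N, nodes = nodes, edges = edges,
                          mixing_outcome = mixing_outcome,
                          mixing_target = M),
                     class = "rds_population")
    pop$truth <- truth_report(pop)
    pop
  })
}

#' @export
print.rds_population <- function(x, ...) {
  cat(sprintf("<rds_population> N = %d, %d edges, mean degree %.2f\n",
              x$N, nrow(x$edges), x$truth$mean_degree))
  cat("outcomes:", paste(names(x$truth$prevalence), collapse = ", "), "\n")
  invisible(x)
}

#' Ground-truth report of a synthetic population
#'
#' Recomputes true prevalences, the realized tie mixing matrix of the
#' structuring outcome and its realized homophily directly from the stored
#' population, so generation-time truth can always be audited.
#'
#' @param population An [sim_population()] result.
#' @return List with `prevalence` (per outcome), `mean_degree`,
#'   `mixing_realized` (row-normalized directed tie mixing),
#'   `homophily_realized` (per group) and the generation-time
#'   `mixing_target`.
#' @export
truth_report <- function(population) {
  stopifnot(inherits(population, "rds_population"))
  nodes <- population$nodes
  ocs <- setdiff(names(nodes), c("id", "degree"))
  prevalence <- lapply(ocs, function(oc) {
    tab <- table(nodes[[oc]])
    stats::setNames(as.vector(tab) / nrow(nodes), names(tab))
  })
  names(prevalence) <- ocs
  groups <- sort(unique(nodes[[population$mixing_outcome]]))
  gidx <- match(nodes[[population$mixing_outcome]], groups)
  e1 <- gidx[population$edges[, 1]]
  e2 <- gidx[population$edges[, 2]]
  # Both directions of every undirected tie.
  mix <- table(factor(c(e1, e2), seq_along(groups)),
               factor(c(e2, e1), seq_along(groups)))
  mix <- matrix(as.numeric(mix), length(groups),
                dimnames = list(groups, groups))
  T_ <- row_normalize(mix)$probs
  e <- rowSums(mix) / sum(mix)
  list(prevalence = prevalence,
       mean_degree = 2 * nrow(population$edges) / population$N,
       mixing_realized = T_,
       homophily_realized = homophily_from(T_, stats::setNames(e, groups)),
       mixing_target = population$mixing_target)
}

#' Simulate coupon-based RDS recruitment over a synthetic population
#'
#' Enrollment proceeds through a FIFO coupon queue: each enrollee receives
#' `coupons` coupons, each of which is returned with probability
#' `return_prob` and, if returned, enrolls a uniformly chosen not-yet-
#' enrolled network neighbour (a returned coupon with no eligible
#' neighbour is wasted; under `replacement = "with"` the neighbour is
#' drawn from all neighbours and the coupon is wasted when the choice is
#' already enrolled — no individual is ever enrolled twice). When the
#' queue empties before the target sample size is reached, fresh seeds are
#' injected uniformly at random among the unenrolled, mirroring the
#' seed top-ups practical RDS studies resort to; the count is logged.
#'
#' @param population An [sim_population()] result.
#' @param n Target sample size (default 719).
#' @param n_seeds Initial number of seeds (default 30).
#' @param coupons Coupons per enrollee (default 6).
#' @param return_prob Per-coupon return probability (default 0.15, giving
#'   roughly 0.9 expected recruits per enrollee — a subcritical chain that
#'   reproduces the seed-heavy recruitment pattern of field studies).
#' @param seed_rule `"uniform"` (default), `"degree"` (probability
#'   proportional to degree) or `"group_stratified"` (equal numbers per
#'   group of the structuring outcome) seed selection.
#' @param replacement `"without"` (default) or `"with"` (see above).
#' @param degree_noise SD of multiplicative log-normal reporting noise on
#'   the emitted network size (default 0, i.e. the true degree).
#' @param seed RNG seed.
#' @return An [rds_forest()] whose ids are the population node ids, with
#'   `enroll_order` filled; attributes `truth` (the population's
#'   [truth_report()]), `seeds_injected` and `complete` (whether the
#'   target n was reached).
#' @export
simulate_rds <- function(population, n = 719, n_seeds = 30, coupons = 6,
                         return_prob = 0.15,
                         seed_rule = c("uniform", "degree",
                                       "group_stratified"),
                         replacement = c("without", "with"),
                         degree_noise = 0, seed = NULL) {
  stopifnot(inherits(population, "rds_population"), coupons >= 1,
            return_prob >= 0, return_prob <= 1)
  seed_rule <- match.arg(seed_rule)
  replacement <- match.arg(replacement)
  N <- population$N
  if (n > N)
    stop_rds("target n exceeds the population size", "rds_validation_error")
  edges <- population$edges
  adj <- split(c(edges[, 2], edges[, 1]),
               factor(c(edges[, 1], edges[, 2]), levels = seq_len(N)))

  with_rng_seed(seed, {
    pick_seeds <- function(k, enrolled) {
      avail <- which(!enrolled)
      k <- min(k, length(avail))
      switch(seed_rule,
        uniform = avail[sample.int(length(avail), k)],
        degree = avail[sample.int(length(avail), k,
                                  prob = population$nodes$degree[avail])],
        group_stratified = {
          grp <- population$nodes[[population$mixing_outcome]][avail]
          ug <- unique(grp)
          per <- ceiling(k / length(ug))
          out <- unlist(lapply(ug, function(g) {
            cand <- avail[grp == g]
            cand[sample.int(length(cand), min(per, length(cand)))]
          }))
          out[seq_len(min(k, length(out)))]
        })
    }
    enrolled <- logical(N)
    order_vec <- integer(0)
    recruiter <- integer(0)  # 0 = seed
    enroll <- function(node, rec) {
      enrolled[node] <<- TRUE
      order_vec[length(order_vec) + 1L] <<- node
      recruiter[length(recruiter) + 1L] <<- rec
    }
    for (s in pick_seeds(min(n_seeds, n), enrolled)) enroll(s, 0L)
    injected <- 0L
    ptr <- 1L
    while (length(order_vec) < n) {
      if (ptr > length(order_vec)) {
        # queue exhausted: inject a fresh seed
        if (all(enrolled)) break
        enroll(pick_seeds(1L, enrolled), 0L)
        injected <- injected + 1L
        next
      }
      cur <- order_vec[ptr]
      returned <- stats::rbinom(1L, coupons, return_prob)
      if (returned > 0) for (k in seq_len(returned)) {
        if (length(order_vec) >= n) break
        nb <- adj[[cur]]
        if (replacement == "without") nb <- nb[!enrolled[nb]]
        if (!length(nb)) next
        cand <- nb[sample.int(length(nb), 1L)]
        if (!enrolled[cand]) enroll(cand, cur)
      }
      ptr <- ptr + 1L
    }

    nodes <- population$nodes
    deg <- nodes$degree[order_vec]
    if (degree_noise > 0)
      deg <- pmax(1, round(deg * exp(stats::rnorm(length(deg), 0,
                                                  degree_noise))))
    tab <- data.frame(
      id = as.character(order_vec),
      recruiter_id = ifelse(recruiter == 0L, NA_character_,
                            as.character(recruiter)),
      degree = deg,
      enroll_order = seq_along(order_vec),
      stringsAsFactors = FALSE)
    for (oc in setdiff(names(nodes), c("id", "degree")))
      tab[[oc]] <- nodes[[oc]][order_vec]
    forest <- rds_forest(tab)
    attr(forest, "truth") <- population$truth
    attr(forest, "seeds_injected") <- injected
    attr(forest, "complete") <- length(order_vec) >= n
    if (!attr(forest, "complete"))
      warning(sprintf("recruitment exhausted at n = %d (target %d)",
                      length(order_vec), n))
    forest
  })
}
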