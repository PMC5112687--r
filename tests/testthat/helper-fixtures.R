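# Fixtures built in code: toy forests and a forest whose chain-structure
# counts match the published bookkeeping table.

toy_forest <- function() {
  rds_forest(data.frame(
    id = c("A", "B", "C", "D"),
    recruiter_id = c("", "A", "B", ""),
    degree = c(2, 3, 1, 5),
    hiv = c("pos", "neg", "pos", "neg"),
    stringsAsFactors = FALSE))
}

# A chain: seed with `depth` waves below it, one member per wave, plus
# `extra` members attached at wave 1.
make_chain <- function(prefix, depth, extra = 0) {
  ids <- paste0(prefix, seq_len(depth + 1))
  rec <- c("", ids[-length(ids)])
  df <- data.frame(id = ids, recruiter_id = rec, stringsAsFactors = FALSE)
  if (extra > 0 && depth >= 1) {
    eid <- paste0(prefix, "x", seq_len(extra))
    df <- rbind(df, data.frame(id = eid,
                               recruiter_id = rep(ids[1], extra),
                               stringsAsFactors = FALSE))
  }
  df
}

# Forest matching the published study's chain structure: n = 719 from 119
# chains; cuts >0 / >1 / >2 leave 669/69, 594/37, 537/25; max depth 16.
# Outcome columns are filled so the published crude numerators hold:
# hiv: 199 positive of 719 (178 within the >1 cut of 594);
# idu: 51 yes within the >0 cut of 669; gay: 612 of 719.
study_shape_forest <- function() {
  chains <- list()
  add <- function(k, depth, extra = 0) {
    for (i in seq_len(k))
      chains[[length(chains) + 1L]] <<-
        make_chain(sprintf("s%03d_", length(chains) + 1L), depth, extra)
  }
  add(50, 0)                   # unproductive seeds: 50 members
  add(31, 1); add(1, 1, 11)    # depth-1: 32 chains, 75 members
  add(11, 2); add(1, 2, 21)    # depth-2: 12 chains, 57 members
  add(1, 16)                   # the max-depth chain: 17 members
  add(15, 3); add(1, 3, 360)   # depth-3 chains
  add(8, 11)                   # deep chains; depths sum to 208 overall
  df <- do.call(rbind, chains)
  stopifnot(nrow(df) == 719)
  df$degree <- 2
  n <- nrow(df)
  df$hiv <- "negative"
  df$idu <- "no"
  df$gay <- "no"
  f0 <- rds_forest(df, outcomes = character(0))
  deep <- f0$seed_id %in% names(chain_depths(f0))[chain_depths(f0) >= 2]
  prod <- f0$seed_id %in% names(chain_depths(f0))[chain_depths(f0) >= 1]
  df$hiv[which(deep)[1:178]] <- "positive"          # 178 inside >1 cut
  df$hiv[which(!deep)[1:21]] <- "positive"          # 199 overall
  df$idu[which(prod)[1:51]] <- "yes"                # 51 inside >0 cut
  df$gay[1:612] <- "yes"                            # 612 overall
  rds_forest(df)
}

# Small synthetic survey reused by several tests (cheap but non-trivial).
small_survey <- function(seed = 42, n = 300, N = 3000) {
  pop <- sim_population(N = N, degree_mean = 8, seed = seed)
  simulate_rds(pop, n = n, n_seeds = 10, return_prob = 0.3,
               seed = seed + 1)
}
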