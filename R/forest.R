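# Recruitment forest: table I/O, wave assignment, chain pruning and the
# seed-productivity cut bookkeeping.

new_rds_forest <- function(df, outcomes) {
  rownames(df) <- NULL
  structure(df, outcomes = outcomes,
            class = c("rds_forest", "data.frame"))
}

#' Build a recruitment forest from a participant table
#'
#' A recruitment forest is the collection of referral chains of an RDS
#' survey: every participant points to their recruiter (seeds point to
#' nobody), carries a self-reported network size (degree) and one column per
#' categorical outcome. Construction validates the table, resolves recruiter
#' links and assigns each participant a wave (graph distance from their
#' chain's seed, with seeds at wave 0) and a chain label (the seed's id).
#'
#' @param records A data.frame with columns `id`, `recruiter_id` (empty,
#'   `NA` or the literal `"seed"` marks a seed), `degree`, optionally
#'   `enroll_order`, plus one column per outcome. Outcome cells left blank
#'   or `NA` are treated as missing (non-response).
#' @param outcomes Character vector naming the outcome columns. Defaults to
#'   every column not otherwise interpreted.
#' @param impute_degree If `TRUE`, rows with a missing or non-positive
#'   degree receive the median degree of their group on the first outcome
#'   (overall median when that is unavailable), with a warning. If `FALSE`
#'   (default) such rows are a validation error.
#' @return An object of class `rds_forest`: the record table augmented with
#'   `wave` and `seed_id` columns. `nrow()` of the forest is the sample
#'   size; `attr(, "outcomes")` names the outcome columns.
#' @seealso [read_recruitment_table()], [prune_by_min_depth()], [cut_report()]
#' @export
rds_forest <- function(records, outcomes = NULL, impute_degree = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("id", "recruiter_id", "degree")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop_rds(paste0("missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "rds_validation_error")

  id <- as.character(records$id)
  if (anyNA(id) || any(!nzchar(id)))
    stop_rds("empty or NA participant id", "rds_validation_error")
  if (anyDuplicated(id))
    stop_rds(paste0("duplicate id(s): ",
                    paste(unique(id[duplicated(id)]), collapse = ", ")),
             "rds_validation_error")

  rec <- as.character(records$recruiter_id)
  rec[is.na(rec) | !nzchar(rec) | tolower(rec) == "seed"] <- NA_character_
  self <- which(!is.na(rec) & rec == id)
  if (length(self))
    stop_rds(paste0("cycle detected: participant(s) recruiting themselves: ",
                    paste(id[self], collapse = ", ")),
             "rds_cycle_error")
  unknown <- which(!is.na(rec) & !(rec %in% id))
  if (length(unknown))
    stop_rds(paste0("recruiter_id referencing unknown id for participant(s): ",
                    paste(id[unknown], collapse = ", ")),
             "rds_validation_error")

  degree <- suppressWarnings(as.numeric(records$degree))
  bad_deg <- which(is.na(degree) | degree < 1)
  if (length(bad_deg)) {
    if (!impute_degree)
      stop_rds(paste0("degree missing or < 1 for participant(s): ",
                      paste(id[bad_deg], collapse = ", ")),
               "rds_validation_error")
    degree[bad_deg] <- NA_real_
  }

  if (is.null(outcomes))
    outcomes <- setdiff(names(records),
                        c("id", "recruiter_id", "degree", "enroll_order",
                          "wave", "seed_id"))
  missing_out <- setdiff(outcomes, names(records))
  if (length(missing_out))
    stop_rds(paste0("outcome column(s) not found: ",
                    paste(missing_out, collapse = ", ")),
             "rds_validation_error")

  if (length(bad_deg)) {
    # Group-median imputation keyed on the first outcome when present.
    key <- if (length(outcomes)) as.character(records[[outcomes[1]]])
           else rep("", length(id))
    med_all <- stats::median(degree, na.rm = TRUE)
    if (is.na(med_all))
      stop_rds("no valid degrees available for imputation",
               "rds_validation_error")
    for (i in bad_deg) {
      grp <- !is.na(key) & key == key[i] & !is.na(degree)
      degree[i] <- if (any(grp)) stats::median(degree[grp]) else med_all
    }
    warning(sprintf("imputed group-median degree for %d record(s): %s",
                    length(bad_deg), paste(id[bad_deg], collapse = ", ")))
  }

  parent <- match(rec, id)
  wave <- ifelse(is.na(parent), 0L, NA_integer_)
  seed_id <- ifelse(is.na(parent), id, NA_character_)
  # Iterative relaxation: order-independent of row order; rows left
  # unresolved at the fixed point lie on a recruiter cycle.
  repeat {
    todo <- which(is.na(wave) & !is.na(wave[parent]))
    if (!length(todo)) break
    wave[todo] <- wave[parent[todo]] + 1L
    seed_id[todo] <- seed_id[parent[todo]]
  }
  if (anyNA(wave))
    stop_rds(paste0("cycle detected among participant(s): ",
                    paste(id[is.na(wave)], collapse = ", ")),
             "rds_cycle_error")

  out <- data.frame(id = id, recruiter_id = rec, degree = degree,
                    stringsAsFactors = FALSE)
  if ("enroll_order" %in% names(records)) {
    eo <- suppressWarnings(as.numeric(records$enroll_order))
    out$enroll_order <- eo
  }
  for (oc in outcomes) {
    v <- as.character(records[[oc]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    out[[oc]] <- v
  }
  out$wave <- wave
  out$seed_id <- seed_id
  new_rds_forest(out, outcomes)
}

#' @export
print.rds_forest <- function(x, ...) {
  dep <- chain_depths(x)
  cat(sprintf(
    "<rds_forest> %d participants in %d chains (%d seeds), max wave %d\n",
    nrow(x), length(dep), sum(x$wave == 0L), max(x$wave)))
  cat("outcomes:", paste(attr(x, "outcomes"), collapse = ", "), "\n")
  invisible(x)
}

#' Maximum wave reached in each recruitment chain
#'
#' @param forest An [rds_forest()].
#' @return Named integer vector, one entry per chain (named by seed id),
#'   giving the chain's depth: the largest wave among its members. An
#'   unproductive seed has depth 0.
#' @export
chain_depths <- function(forest) {
  stopifnot(inherits(forest, "rds_forest"))
  d <- tapply(forest$wave, forest$seed_id, max)
  stats::setNames(as.integer(d), names(d))
}

#' Drop recruitment chains shallower than a productivity threshold
#'
#' Reproduces the seed-productivity sample cuts used in seed-sensitivity
#' analyses: the `c = 0` cut removes unproductive seeds (chains of depth 0),
#' `c = 1` removes chains of at most one wave, and so on. A chain is kept,
#' with all of its members, exactly when its depth is at least `c + 1`.
#'
#' @param forest An [rds_forest()].
#' @param c Minimum-depth cut, a non-negative integer.
#' @return A new `rds_forest` containing the surviving chains (possibly
#'   empty); the input is not modified.
#' @export
prune_by_min_depth <- function(forest, c) {
  stopifnot(inherits(forest, "rds_forest"), length(c) == 1, c >= 0)
  dep <- chain_depths(forest)
  keep_seeds <- names(dep)[dep >= c + 1]
  keep <- forest$seed_id %in% keep_seeds
  new_rds_forest(as.data.frame(forest)[keep, , drop = FALSE],
                 attr(forest, "outcomes"))
}

#' Bookkeeping table for a set of seed-productivity cuts
#'
#' For the overall sample and each requested cut, tabulates the remaining
#' sample size, number of seeds (equivalently, chains), the seeds' share of
#' the remaining sample, how many participants the cut removed relative to
#' the overall sample, and chain-length summaries (the wave statistics are
#' taken over chain depths, one value per chain). Display percentages are
#' rounded half-away-from-zero to one decimal.
#'
#' @param overall The full [rds_forest()].
#' @param cuts Integer vector of minimum-depth cuts (default `c(0, 1, 2)`);
#'   each is applied with [prune_by_min_depth()].
#' @param cut_forests Optional named list of pre-pruned forests (names are
#'   the cut values) to report on instead of pruning internally; each must
#'   be a subset of `overall`.
#' @return A data.frame with one row per cut (the overall sample first).
#' @export
cut_report <- function(overall, cuts = c(0, 1, 2), cut_forests = NULL) {
  stopifnot(inherits(overall, "rds_forest"))
  if (is.null(cut_forests)) {
    cut_forests <- lapply(cuts, function(ci) prune_by_min_depth(overall, ci))
    names(cut_forests) <- as.character(cuts)
  } else {
    cuts <- as.numeric(names(cut_forests))
    for (f in cut_forests)
      if (!all(f$id %in% overall$id))
        stop_rds("cut forest is not a subset of the overall forest",
                 "rds_consistency_error")
  }
  n_all <- nrow(overall)
  row_for <- function(label, cval, f) {
    n <- nrow(f)
    n_seeds <- if (n) sum(f$wave == 0L) else 0L
    dep <- if (n) chain_depths(f) else integer()
    data.frame(
      cut = label, min_depth = cval,
      n_remaining = n, n_seeds = n_seeds,
      seeds_pct_of_sample = if (n) round_half_out(pct(n_seeds, n)) else NA_real_,
      n_removed_vs_overall = n_all - n,
      removed_pct_of_overall = round_half_out(pct(n_all - n, n_all)),
      wave_mean = if (n) mean(dep) else NA_real_,
      wave_median = if (n) stats::median(dep) else NA_real_,
      wave_min = if (n) min(dep) else NA_integer_,
      wave_max = if (n) max(dep) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  rows <- c(list(row_for("overall", NA_real_, overall)),
            mapply(function(ci, f) row_for(paste0(">", ci), ci, f),
                   cuts, cut_forests, SIMPLIFY = FALSE))
  do.call(rbind, rows)
}

#' Read a recruitment table from CSV
#'
#' Expects a comma-separated, UTF-8 file with a header row. A seed is
#' denoted by an empty recruiter cell (the literal `"seed"` is also
#' accepted); blank outcome cells are recorded as missing.
#'
#' @param source Path or connection to the CSV file.
#' @param schema Named list mapping the roles `id`, `recruiter`, `degree`
#'   and (optionally) `enroll_order` to column names in the file.
#' @param outcomes Character vector of outcome column names; default all
#'   remaining columns.
#' @inheritParams rds_forest
#' @return An [rds_forest()].
#' @export
read_recruitment_table <- function(source,
                                   schema = list(id = "id",
                                                 recruiter = "recruiter_id",
                                                 degree = "degree",
                                                 enroll_order = "enroll_order"),
                                   outcomes = NULL,
                                   impute_degree = FALSE) {
  df <- utils::read.csv(source, colClasses = "character",
                        check.names = FALSE, na.strings = character())
  need <- c(schema$id, schema$recruiter, schema$degree)
  absent <- setdiff(need, names(df))
  if (length(absent))
    stop_rds(paste0("column(s) not in file: ", paste(absent, collapse = ", ")),
             "rds_validation_error")
  ren <- c(id = schema$id, recruiter_id = schema$recruiter,
           degree = schema$degree)
  if (!is.null(schema$enroll_order) && schema$enroll_order %in% names(df))
    ren <- c(ren, enroll_order = schema$enroll_order)
  for (k in names(ren)) names(df)[names(df) == ren[[k]]] <- k
  rds_forest(df, outcomes = outcomes, impute_degree = impute_degree)
}

#' Write a recruitment forest back to CSV
#'
#' Missing outcome cells and the recruiter cell of seeds serialize as empty
#' strings, so a write/read round trip reproduces the forest.
#'
#' @param forest An [rds_forest()].
#' @param path Destination file path or connection.
#' @param derived Include the derived `wave` and `seed_id` columns
#'   (default `FALSE`, so the file matches the input contract of
#'   [read_recruitment_table()]).
#' @return `path`, invisibly.
#' @export
write_recruitment_table <- function(forest, path, derived = FALSE) {
  stopifnot(inherits(forest, "rds_forest"))
  df <- as.data.frame(forest)
  if (!derived) df$wave <- df$seed_id <- NULL
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export the recruitment forest as a child–parent edge list
#'
#' @param forest An [rds_forest()].
#' @return A data.frame with columns `child` and `parent`, one row per
#'   recruitment event (seeds do not appear as children); suitable for
#'   external tree-drawing tools.
#' @export
export_edge_list <- function(forest) {
  stopifnot(inherits(forest, "rds_forest"))
  kids <- !is.na(forest$recruiter_id)
  data.frame(child = forest$id[kids], parent = forest$recruiter_id[kids],
             stringsAsFactors = FALSE)
}
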