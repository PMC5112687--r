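# End-to-end pipeline: configuration validation, stage orchestration
# (read/simulate -> cuts -> estimates -> diagnostics -> comparison) and
# report assembly. The package's functions are the primary interface; the
# pipeline exists so a whole analysis is reproducible from one config.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or YAML file) with either an `input`
#' path to a recruitment CSV or a `simulate` block (arguments for
#' [sim_population()] and [simulate_rds()]), plus analysis settings. All
#' fields are validated before any stage runs, and the full configuration
#' is serialized into every output for provenance.
#'
#' @param config Named list or path to a YAML file.
#' @return The validated config (class `rds_run_config`) with defaults
#'   filled in.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config))
    stop_rds("config must be a named list or YAML path", "rds_config_error")
  defaults <- list(outcomes = NULL,
                   estimators = c("rds_i", "rds_ii", "rds_ss"),
                   N = NULL, cuts = c(0, 1, 2), B = 1000,
                   replicates = 100, tree_fraction = 0.5, alpha = 0.05,
                   epsilon = 0.01, rng_seed = 1, diagnostics = TRUE,
                   comparison = TRUE, denominator = "all_records",
                   ci_method = "normal")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (is.null(config$input) && is.null(config$simulate))
    stop_rds("config needs either 'input' (CSV path) or a 'simulate' block",
             "rds_config_error")
  if (!is.null(config$input) && !is.null(config$simulate))
    stop_rds("config cannot have both 'input' and 'simulate'",
             "rds_config_error")
  if (!is.null(config$input) && !file.exists(config$input))
    stop_rds(paste0("input file not found: ", config$input),
             "rds_config_error")
  if ("rds_ss" %in% config$estimators && is.null(config$N))
    stop_rds("estimator rds_ss requested but population size N missing",
             "rds_config_error")
  structure(config, class = c("rds_run_config", "list"))
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                              name))
  tryCatch(expr, error = function(e) {
    stop_rds(sprintf("stage '%s' failed: %s (check the config fields this stage uses)",
                     name, conditionMessage(e)), "rds_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes read-or-simulate, cut bookkeeping, estimation with bootstrap
#' CIs across cuts, diagnostics (convergence/bottleneck series, homophily,
#' waves to equilibrium) and the seed-tree estimator comparison, then
#' writes a CSV/JSON bundle plus a human-readable summary.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @param output_dir Directory for the report bundle; created if missing.
#'   `NULL` skips writing and just returns the bundle.
#' @param quiet Suppress stage messages.
#' @return The report bundle (list), invisibly when written.
#' @export
run_pipeline <- function(config, output_dir = NULL, quiet = FALSE) {
  config <- run_config(config)
  seed <- config$rng_seed
  bundle <- list(config = unclass(config), warnings = character(0))

  forest <- pipeline_stage("input", quiet, {
    if (!is.null(config$input)) {
      read_recruitment_table(config$input, outcomes = config$outcomes)
    } else {
      sim <- config$simulate
      pop_args <- sim[intersect(names(sim),
                                names(formals(sim_population)))]
      pop_args$seed <- derive_seed(seed, 1)
      pop <- do.call(sim_population, pop_args)
      rds_args <- sim[intersect(names(sim), names(formals(simulate_rds)))]
      rds_args$population <- pop
      rds_args$seed <- derive_seed(seed, 2)
      f <- do.call(simulate_rds, rds_args)
      # evaluated in run_pipeline's frame, so plain `<-` updates the bundle
      bundle$truth <- attr(f, "truth")
      if (attr(f, "seeds_injected") > 0)
        bundle$warnings <- c(bundle$warnings,
                             sprintf("%d seed(s) injected during recruitment",
                                     attr(f, "seeds_injected")))
      f
    }
  })
  outcomes <- config$outcomes %||% attr(forest, "outcomes")

  sens <- pipeline_stage("cut analysis", quiet,
    run_cut_analysis(forest, outcomes = outcomes,
                     estimators = config$estimators, N = config$N,
                     B = config$B, seed = derive_seed(seed, 3),
                     cuts = config$cuts, denominator = config$denominator,
                     ci_method = config$ci_method))
  bundle$cut_summary <- sens$cut_summary
  bundle$estimates <- rbind(sens$crude, sens$estimates)
  bundle$containment <- sens$containment
  bundle$warnings <- c(bundle$warnings, sens$notes)

  if (isTRUE(config$diagnostics)) {
    bundle$diagnostics <- pipeline_stage("diagnostics", quiet, {
      lapply(stats::setNames(outcomes, outcomes), function(oc) {
        conv <- convergence_series(forest, oc, estimator = "rds_ii")
        bots <- suppressMessages(
          bottleneck_series(forest, oc, estimator = "rds_ii"))
        model <- tryCatch(build_transition_model(forest, oc),
                          error = function(e) NULL)
        list(convergence = conv, bottleneck = bots, model = model,
             homophily = if (!is.null(model)) homophily_index(model),
             equilibrium = if (!is.null(model))
               equilibrium_waves(model, epsilon = config$epsilon))
      })
    })
  }

  if (isTRUE(config$comparison)) {
    bundle$comparison <- pipeline_stage("comparison", quiet,
      compare_estimators_simulation(
        forest, outcomes = outcomes,
        estimators = union("crude", config$estimators),
        replicates = config$replicates,
        tree_fraction = config$tree_fraction, alpha = config$alpha,
        seed = derive_seed(seed, 4), N = config$N,
        denominator = config$denominator))
  }
  bundle$forest <- forest

  if (is.null(output_dir)) return(bundle)
  pipeline_stage("write", quiet, write_bundle(bundle, output_dir))
  invisible(bundle)
}

write_bundle <- function(bundle, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(bundle$config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  stamp <- c(sprintf("# config_hash: %s", content_hash(cfg_json)),
             sprintf("# rng_seed: %s", bundle$config$rng_seed))
  wcsv <- function(df, file) {
    path <- file.path(output_dir, file)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE, na = "")
    close(con)
  }
  wcsv(bundle$cut_summary, "cut_summary.csv")
  wcsv(bundle$estimates, "estimates.csv")
  if (!is.null(bundle$containment)) wcsv(bundle$containment,
                                         "containment.csv")
  if (!is.null(bundle$diagnostics)) {
    ser <- do.call(rbind, lapply(bundle$diagnostics, function(d)
      rbind(series_table(d$convergence), series_table(d$bottleneck))))
    wcsv(ser, "diagnostic_series.csv")
  }
  if (!is.null(bundle$comparison)) {
    wcsv(bundle$comparison$summary, "comparison_summary.csv")
    wcsv(bundle$comparison$pairwise, "comparison_pairwise.csv")
  }
  write_recruitment_table(bundle$forest,
                          file.path(output_dir, "recruitment_table.csv"),
                          derived = TRUE)
  utils::write.csv(export_edge_list(bundle$forest),
                   file.path(output_dir, "edge_list.csv"),
                   row.names = FALSE)
  meta <- list(config = bundle$config,
               config_hash = content_hash(cfg_json),
               warnings = bundle$warnings,
               truth = bundle$truth)
  jsonlite::write_json(meta, file.path(output_dir, "run_meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  writeLines(render_summary(bundle), file.path(output_dir, "summary.md"))
  invisible(output_dir)
}

#' Render a human-readable markdown summary of a pipeline bundle
#'
#' @param bundle A [run_pipeline()] result.
#' @return Character vector of markdown lines.
#' @export
render_summary <- function(bundle) {
  fmt_tab <- function(df) {
    if (is.null(df) || !nrow(df)) return("(empty)")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) round(x, 2))
    c(paste("|", paste(names(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      apply(df, 1, function(r)
        paste("|", paste(r, collapse = " | "), "|")))
  }
  out <- c("# RDS analysis summary", "",
           sprintf("- rng_seed: %s", bundle$config$rng_seed %||% "NA"),
           sprintf("- config_hash: %s",
                   content_hash(jsonlite::toJSON(bundle$config,
                                                 auto_unbox = TRUE,
                                                 digits = NA,
                                                 null = "null"))), "")
  out <- c(out, "## Sample cuts", "", fmt_tab(bundle$cut_summary), "")
  out <- c(out, "## Estimates", "", fmt_tab(bundle$estimates), "")
  if (!is.null(bundle$containment)) {
    bad <- bundle$containment[!bundle$containment$within, , drop = FALSE]
    out <- c(out, "## Crude-within-CI containment", "",
             sprintf("%d of %d cells contained.",
                     sum(bundle$containment$within),
                     nrow(bundle$containment)), "")
    if (nrow(bad))
      out <- c(out, "**Containment failures:**", "", fmt_tab(bad), "")
  }
  if (!is.null(bundle$diagnostics)) {
    out <- c(out, "## Diagnostics", "")
    for (oc in names(bundle$diagnostics)) {
      d <- bundle$diagnostics[[oc]]
      if (is.null(d$model)) next
      out <- c(out, sprintf(
        "- %s: homophily %s; waves to equilibrium (eps = %g): %s",
        oc, paste(sprintf("%s=%.3f", names(d$homophily), d$homophily),
                  collapse = ", "),
        d$equilibrium$epsilon, format(d$equilibrium$waves_max)))
    }
    out <- c(out, "")
  }
  if (!is.null(bundle$comparison)) {
    out <- c(out, "## Estimator comparison", "",
             fmt_tab(bundle$comparison$pairwise), "")
  }
  if (length(bundle$warnings))
    out <- c(out, "## Warnings", "", paste("-", bundle$warnings), "")
  out
}
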