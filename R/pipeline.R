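#' Analysis configuration
#'
#' Bundles everything [run_full_analysis()] needs: the input (a study CSV
#' or a synthetic-generator config), prediction horizons, bootstrap size,
#' the master seed, tie handling, the Rubin's B/R scale, the output
#' directory and an optional column map. Config files are JSON.
#'
#' @param input path of a patient-level study CSV, or NULL to simulate.
#' @param synthetic generate data with [generate_cohort()] (default when
#'   `input` is NULL).
#' @param synthetic_cfg a [synthetic_config()].
#' @param horizons positive ascending horizons in days.
#' @param n_bootstrap bootstrap replicates (>= 1).
#' @param seed master seed; every source of randomness derives from it via
#'   [seed_streams()].
#' @param ties Cox tie handling.
#' @param balance_scale scale for Rubin's B/R ("ps" or "logit").
#' @param out_dir output directory for report files.
#' @param column_map optional column-name map for `input`.
#' @param do_bootstrap run the bootstrap stage (default TRUE).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(input = NULL, synthetic = is.null(input),
                            synthetic_cfg = synthetic_config(),
                            horizons = c(365, 730, 1095),
                            n_bootstrap = 1000L, seed = 1L,
                            ties = c("efron", "breslow"),
                            balance_scale = c("ps", "logit"),
                            out_dir = tempfile("navsurv_run_"),
                            column_map = NULL, do_bootstrap = TRUE) {
  ties <- match.arg(ties)
  balance_scale <- match.arg(balance_scale)
  if (any(diff(horizons) <= 0) || any(horizons <= 0))
    ns_stop("navsurv_config_error", "horizons must be positive and ascending")
  if (n_bootstrap < 1L)
    ns_stop("navsurv_config_error", "n_bootstrap must be >= 1")
  structure(list(input = input, synthetic = synthetic,
                 synthetic_cfg = synthetic_cfg, horizons = horizons,
                 n_bootstrap = as.integer(n_bootstrap), seed = as.integer(seed),
                 ties = ties, balance_scale = balance_scale,
                 out_dir = out_dir, column_map = column_map,
                 do_bootstrap = do_bootstrap),
            class = "analysis_config")
}

#' Read an analysis configuration from a JSON file
#' @param path JSON file with fields named as in [analysis_config()].
#' @return `analysis_config` object.
#' @export
read_analysis_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw[intersect(names(raw),
                        names(formals(analysis_config)))]
  do.call(analysis_config, args)
}

#' Run the full survival-impact analysis
#'
#' Executes the whole chain: read (or generate + eligibility-filter) the
#' two-cohort table, fit the propensity model, compute SMR (ATT) weights,
#' build the balance table with Rubin's B/R, estimate unweighted and
#' weighted Kaplan-Meier curves with log-rank tests, fit the three Cox
#' specifications (univariate, all-baseline, all-post-baseline), run the
#' counterfactual g-computation with bootstrap, and produce the delay and
#' process/outcome descriptive tables. Writes CSV reports, a KM plot and a
#' run log into the output directory; byte-identical outputs under a fixed
#' seed.
#'
#' @param config an [analysis_config()].
#' @return invisible list with every intermediate object (records, weights,
#'   balance, km, logrank, cox fits, counterfactual, descriptives, paths).
#' @export
run_full_analysis <- function(config = analysis_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  log_con <- file(log_path, open = "wt")
  on.exit(close(log_con))
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "[%H:%M:%S] "), ...)
    writeLines(line, log_con)
    message(line)
  }
  stage <- "setup"
  result <- tryCatch({
    logmsg("navsurv ", as.character(utils::packageVersion("navsurv")),
           " on ", R.version.string)
    logmsg("master seed: ", config$seed)
    seeds <- seed_streams(config$seed, 2)

    stage <- "input"
    records <- if (!is.null(config$input)) {
      read_study_table(config$input, column_map = config$column_map)
    } else {
      logmsg("generating synthetic cohort (generator seed ", seeds[1], ")")
      generate_cohort(config$synthetic_cfg, seed = seeds[1])
    }
    tab <- table(records$cohort)
    logmsg("records: ", nrow(records), " (",
           paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "),
           "); deaths: ",
           paste(sprintf("%s = %d", names(tab),
                         as.integer(tapply(records$event, records$cohort, sum))),
                 collapse = ", "))

    stage <- "propensity"
    prop <- fit_propensity(records)
    if (length(prop$dropped_terms))
      logmsg("propensity model dropped zero-variance term(s): ",
             paste(prop$dropped_terms, collapse = ", "))
    weights <- compute_smr_weights(prop$ps, records$cohort)
    logmsg("sum of control weights (effective matched controls): ",
           round(sum(weights[records$cohort == "control"]), 1))

    stage <- "balance"
    balance <- balance_table(records, weights, prop$ps,
                             scale = config$balance_scale)
    rb <- attr(balance, "rubins")
    logmsg(sprintf("Rubin's B %.3f -> %.3f; R %.3f -> %.3f",
                   rb$b_unweighted, rb$b_weighted,
                   rb$r_unweighted, rb$r_weighted))
    utils::write.csv(cbind(as.data.frame(balance)),
                     file.path(config$out_dir, "table1_balance.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(rb, auto_unbox = TRUE, digits = NA),
               file.path(config$out_dir, "rubins.json"))

    stage <- "kaplan-meier"
    km <- list()
    lr <- list()
    for (wtag in c("unweighted", "weighted")) {
      w <- if (wtag == "weighted") weights else rep(1, nrow(records))
      km[[wtag]] <- lapply(stats::setNames(nm = levels(records$cohort)), function(coh) {
        idx <- records$cohort == coh
        weighted_km(records$followup_days[idx], records$event[idx], w[idx],
                    label = paste(coh, wtag))
      })
      lr[[wtag]] <- weighted_logrank(records$followup_days, records$event, w,
                                     records$cohort)
      logmsg(wtag, " log-rank p = ", signif(lr[[wtag]]$p, 3))
    }
    km_df <- do.call(rbind, lapply(names(km), function(wtag)
      do.call(rbind, lapply(names(km[[wtag]]), function(coh)
        cbind(weighting = wtag, cohort = coh,
              as.data.frame(km[[wtag]][[coh]]))))))
    utils::write.csv(km_df, file.path(config$out_dir, "km_curves.csv"),
                     row.names = FALSE)
    plot_path <- file.path(config$out_dir, "km_plot.pdf")
    plot_km_pair(km, plot_path)

    stage <- "cox"
    specs <- model_specifications()
    cox_fits <- lapply(specs, function(terms)
      fit_weighted_cox(records, weights, terms = terms, ties = config$ties))
    tab2 <- do.call(rbind, lapply(names(cox_fits), function(nm)
      cbind(model = nm, cox_table(cox_fits[[nm]]))))
    utils::write.csv(tab2, file.path(config$out_dir, "table2_cox.csv"),
                     row.names = FALSE)
    logmsg("univariate intervention HR = ",
           sprintf("%.2f [%.2f-%.2f]", cox_fits$univariate$hr["cohortintervention"],
                   cox_fits$univariate$ci_lower["cohortintervention"],
                   cox_fits$univariate$ci_upper["cohortintervention"]))

    stage <- "counterfactual"
    cf <- NULL
    if (config$do_bootstrap) {
      if (config$n_bootstrap < 1000L)
        logmsg("NOTE: reduced-replicate mode (n_bootstrap = ",
               config$n_bootstrap, " < 1000)")
      cf <- bootstrap_effect(records, config$horizons,
                             n_bootstrap = config$n_bootstrap,
                             seed = seeds[2], ties = config$ties)
      utils::write.csv(counterfactual_table(cf),
                       file.path(config$out_dir, "table3_counterfactual.csv"))
      logmsg("counterfactual point effect (pp): ",
             paste(sprintf("%+.1f", 100 * cf$effect), collapse = " / "),
             "; P(effect > 0): ",
             paste(sprintf("%.1f%%", 100 * cf$prob_positive), collapse = " / "))
    } else {
      cf <- gcomputation_effect(records, weights, config$horizons,
                                ties = config$ties)
      logmsg("counterfactual point effect (pp): ",
             paste(sprintf("%+.1f", 100 * cf$effect), collapse = " / "))
    }

    stage <- "descriptives"
    delays <- summarize_delays(records, weights)
    procs_w <- summarize_process_and_outcomes(records, weights)
    procs_u <- summarize_process_and_outcomes(records)
    utils::write.csv(delays, file.path(config$out_dir, "delays.csv"),
                     row.names = FALSE)
    utils::write.csv(procs_w, file.path(config$out_dir,
                                        "process_outcomes_weighted.csv"),
                     row.names = FALSE)
    utils::write.csv(procs_u, file.path(config$out_dir,
                                        "process_outcomes_unweighted.csv"),
                     row.names = FALSE)
    logmsg("run complete; outputs in ", config$out_dir)

    list(config = config, records = records, propensity = prop,
         weights = weights, balance = balance, km = km, logrank = lr,
         cox = cox_fits, counterfactual = cf,
         descriptives = list(delays = delays, process_weighted = procs_w,
                             process_unweighted = procs_u),
         out_dir = config$out_dir, log = log_path)
  }, error = function(e) {
    logmsg("ERROR in stage '", stage, "': ", conditionMessage(e))
    ns_stop("navsurv_pipeline_error",
            "analysis aborted in stage '", stage, "': ", conditionMessage(e))
  })
  invisible(result)
}

# two-panel KM plot (unweighted / weighted); base graphics, PDF device
plot_km_pair <- function(km, path) {
  grDevices::pdf(path, width = 9, height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 2))
  for (wtag in names(km)) {
    graphics::plot(NULL, xlim = c(0, max(vapply(km[[wtag]], function(k)
      max(c(k$time, 1)), numeric(1)))), ylim = c(0, 1),
      xlab = "days since first cancer-suspect code",
      ylab = "overall survival", main = wtag)
    cols <- c(control = "grey40", intervention = "firebrick")
    for (coh in names(km[[wtag]])) {
      k <- km[[wtag]][[coh]]
      graphics::lines(stats::stepfun(k$time, c(1, k$survival)),
                      do.points = FALSE, col = cols[[coh]])
    }
    graphics::legend("topright", legend = names(km[[wtag]]),
                     col = cols[names(km[[wtag]])], lty = 1, bty = "n")
  }
  invisible(path)
}

#' Command-line interface
#'
#' Subcommands: `simulate` (write a synthetic study table), `analyze`
#' (everything except the bootstrap), `bootstrap` (counterfactual bootstrap
#' only), `report` (the full chain). Flags: `--input`, `--config`,
#' `--seed`, `--n-bootstrap`, `--horizons` (comma-separated days),
#' `--out`.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
navsurv_cli <- function(args = commandArgs(TRUE)) {
  usage <- paste(
    "usage: navsurv <simulate|analyze|bootstrap|report> [--input PATH]",
    "[--config PATH] [--seed INT] [--n-bootstrap INT]",
    "[--horizons D1,D2,...] [--out DIR]")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1L]
  flags <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) { message("missing value for --", key); return(invisible(1L)) }
    flags[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(flags[["seed"]] %||% 1L)
  out <- flags[["out"]] %||% "."
  horizons <- if (!is.null(flags[["horizons"]]))
    as.numeric(strsplit(flags[["horizons"]], ",")[[1]]) else c(365, 730, 1095)
  n_boot <- as.integer(flags[["n-bootstrap"]] %||% 1000L)

  status <- tryCatch({
    cfg <- if (!is.null(flags[["config"]])) read_analysis_config(flags[["config"]])
           else analysis_config(input = flags[["input"]], horizons = horizons,
                                n_bootstrap = n_boot, seed = seed, out_dir = out)
    cfg$seed <- seed; cfg$out_dir <- out
    cfg$n_bootstrap <- n_boot; cfg$horizons <- horizons
    if (cmd == "simulate") {
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      rec <- generate_cohort(cfg$synthetic_cfg, seed = seed)
      write_study_table(rec, file.path(out, "synthetic_cohort.csv"))
      message("wrote ", file.path(out, "synthetic_cohort.csv"))
    } else if (cmd == "analyze") {
      cfg$do_bootstrap <- FALSE
      run_full_analysis(cfg)
    } else if (cmd == "bootstrap") {
      records <- if (!is.null(cfg$input)) read_study_table(cfg$input,
                                                           column_map = cfg$column_map)
                 else generate_cohort(cfg$synthetic_cfg, seed = seed_streams(seed, 2)[1])
      cf <- bootstrap_effect(records, horizons, n_bootstrap = n_boot,
                             seed = seed_streams(seed, 2)[2])
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(counterfactual_table(cf),
                       file.path(out, "table3_counterfactual.csv"))
      print(cf)
    } else if (cmd == "report") {
      run_full_analysis(cfg)
    } else {
      message("unknown subcommand '", cmd, "'\n", usage)
      return(invisible(1L))
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
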