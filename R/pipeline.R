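#' Configure an end-to-end analysis run
#'
#' Either a synthetic deployment (a \code{\link{deployment_config}}) or real
#' tag exports (logger and feeding CSV paths) feed the pipeline; exactly one
#' of the two must be given.
#'
#' @param synthetic a \code{\link{deployment_config}}, or \code{NULL}.
#' @param logger_csv,feeding_csv paths to real tag exports, or \code{NULL}.
#' @param hr_low,hr_high,qi_reject QC rules (see
#'   \code{\link{filter_records}}).
#' @param quantile_type quantile convention for daily aggregation.
#' @param models list of \code{\link{model_spec}}s to fit; defaults to the
#'   full nested set of \code{\link{enumerate_models}}.
#' @param mcmc a \code{\link{mcmc_config}} applied to every model (its seed
#'   is fanned out per model from the pipeline seed).
#' @param out_dir output directory for run artifacts.
#' @param seed global pipeline seed; stage seeds derive from it by fixed
#'   offsets so stages are independently reproducible.
#' @export
pipeline_config <- function(synthetic = NULL, logger_csv = NULL,
                            feeding_csv = NULL, hr_low = 8, hr_high = 120,
                            qi_reject = c(2, 3), quantile_type = 7,
                            models = NULL, mcmc = mcmc_config(),
                            out_dir = tempfile("ctag_run_"), seed = 1L) {
  has_synth <- !is.null(synthetic)
  has_files <- !is.null(logger_csv) || !is.null(feeding_csv)
  if (has_synth && has_files)
    stop("configuration error: give either a synthetic config or input ",
         "paths, not both")
  if (!has_synth && (is.null(logger_csv) || is.null(feeding_csv)))
    stop("configuration error: need a synthetic config, or both logger_csv ",
         "and feeding_csv")
  if (has_synth) stopifnot(inherits(synthetic, "ctag_config"))
  if (is.null(models)) models <- enumerate_models()
  structure(list(synthetic = synthetic, logger_csv = logger_csv,
                 feeding_csv = feeding_csv, hr_low = hr_low,
                 hr_high = hr_high, qi_reject = qi_reject,
                 quantile_type = quantile_type, models = models,
                 mcmc = mcmc, out_dir = out_dir, seed = as.integer(seed)),
            class = "ctag_pipeline")
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or load) logger records and the feeding log; quality
#' control; daily aggregation; MCMC fit of every candidate model; DIC
#' ranking; posterior predictions from the best model. Artifacts are written
#' under \code{config$out_dir}: \code{logger.csv}, \code{feeding.csv},
#' \code{qc_report.txt}, \code{daily_summaries.csv}, \code{ranking.csv}
#' (model, pD, DIC, dDIC, R2), \code{best_model_params.csv} (parameter,
#' estimate, sd, q2.5, q97.5), \code{predictions.csv} (date, observed HRm,
#' posterior-mean prediction and 95\% credible envelope) and
#' \code{manifest.txt} recording the configuration, seed and stage row
#' counts. Identical config and seed give identical artifacts.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress stage messages.
#' @return (invisibly) list of in-memory artifacts: \code{records},
#'   \code{feeding}, \code{qc}, \code{daily}, \code{fits}, \code{ranking},
#'   \code{best_fit}, \code{predictions}, \code{out_dir}.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ctag_pipeline"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  # stage 1: acquire records
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    syn$seed <- config$seed
    say("simulate: ", syn$n_days, " days x ", syn$records_per_day,
        " records/day")
    sim <- simulate_deployment(syn)
    records <- sim$records
    feeding <- sim$feeding
  } else {
    say("load: ", config$logger_csv)
    records <- read_logger_csv(config$logger_csv)
    feeding <- read_feeding_csv(config$feeding_csv)
  }
  write_logger_csv(records, file.path(config$out_dir, "logger.csv"))
  write_feeding_csv(feeding, file.path(config$out_dir, "feeding.csv"))

  # stage 2: QC
  qc <- filter_records(records, hr_low = config$hr_low,
                       hr_high = config$hr_high,
                       qi_reject = config$qi_reject)
  say("qc: kept ", qc$report$n_kept, "/", qc$report$n_total, " records (",
      sprintf("%.1f%%", 100 * qc$report$pass_fraction), ")")
  writeLines(utils::capture.output(print(qc$report)),
             file.path(config$out_dir, "qc_report.txt"))

  # stage 3: daily aggregation
  daily <- daily_summaries(qc$records, feeding,
                           quantile_type = config$quantile_type)
  say("aggregate: ", nrow(daily), " days")
  write_daily_csv(daily, file.path(config$out_dir, "daily_summaries.csv"))

  # stage 4: fit candidate models (per-model seeds fan out from the global)
  fits <- vector("list", length(config$models))
  for (i in seq_along(config$models)) {
    mc <- config$mcmc
    mc$seed <- config$seed + 100L * i
    say("fit ", i, "/", length(config$models), ": ",
        config$models[[i]]$label)
    fits[[i]] <- fit_model(config$models[[i]], daily, mcmc = mc)
  }

  # stage 5: rank and predict from the best model
  ranking <- select_best(fits)
  best_fit <- fits[[ranking$order_in[1]]]
  preds <- predict_hrm(best_fit, daily)
  say("select: best model is ", ranking$model[1])

  rank_out <- data.frame(model = ranking$model,
                         n_params = ranking$n_params,
                         pD = signif(ranking$pD, 6),
                         DIC = signif(ranking$DIC, 6),
                         dDIC = signif(ranking$dDIC, 6),
                         R2 = signif(ranking$R2, 6))
  write.csv(rank_out, file.path(config$out_dir, "ranking.csv"),
            row.names = FALSE, quote = FALSE)
  bs <- best_fit$summary
  write.csv(data.frame(parameter = bs$parameter,
                       estimate = signif(bs$estimate, 6),
                       sd = signif(bs$sd, 6),
                       q2.5 = signif(bs$q2.5, 6),
                       q97.5 = signif(bs$q97.5, 6),
                       rhat = signif(bs$rhat, 6)),
            file.path(config$out_dir, "best_model_params.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(date = as.character(preds$date), hrm = preds$HRm,
                       fit = signif(preds$fit, 6),
                       lwr = signif(preds$lwr, 6),
                       upr = signif(preds$upr, 6)),
            file.path(config$out_dir, "predictions.csv"),
            row.names = FALSE, quote = FALSE)

  manifest <- c(
    "cardiotag pipeline manifest",
    paste0("seed = ", config$seed),
    paste0("source = ", if (is.null(config$synthetic)) "files" else
      "synthetic"),
    paste0("n_records_in = ", qc$report$n_total),
    paste0("n_records_kept = ", qc$report$n_kept),
    paste0("n_records_dropped = ", qc$report$n_total - qc$report$n_kept),
    paste0("n_days_summarised = ", nrow(daily)),
    paste0("n_days_omitted = ", length(attr(daily, "omitted_dates"))),
    paste0("n_models = ", length(fits)),
    paste0("mcmc = ", config$mcmc$n_chains, " chains x (",
           config$mcmc$n_burn, " burn + ", config$mcmc$n_keep, " keep)"),
    paste0("best_model = ", ranking$model[1]))
  writeLines(manifest, file.path(config$out_dir, "manifest.txt"))

  invisible(list(records = records, feeding = feeding, qc = qc$report,
                 daily = daily, fits = fits, ranking = ranking,
                 best_fit = best_fit, predictions = preds,
                 out_dir = config$out_dir))
}

#' Render a plain-text analysis report
#'
#' Deterministic human-readable summary of a pipeline run: QC pass fraction,
#' the DIC ranking with the best model flagged at \code{dDIC = 0}, and the
#' best model's parameter table.
#'
#' @param artifacts list returned by \code{\link{run_pipeline}}.
#' @param path optional file to write the report to.
#' @return character vector of report lines (invisibly if written to file).
#' @export
render_report <- function(artifacts, path = NULL) {
  need <- c("qc", "ranking", "best_fit", "daily")
  miss <- setdiff(need, names(artifacts))
  if (length(miss)) stop("report error: missing artifact(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(artifacts$ranking) == 0) stop("report error: empty model ranking")
  rk <- artifacts$ranking
  bf <- artifacts$best_fit
  fmt6 <- function(x) formatC(signif(x, 6), format = "g")
  lines <- c(
    "== Heart-rate deployment analysis ==",
    sprintf("Records: %d total, %d kept (QC pass fraction %s)",
            artifacts$qc$n_total, artifacts$qc$n_kept,
            fmt6(artifacts$qc$pass_fraction)),
    sprintf("Days modelled: %d", nrow(artifacts$daily)),
    "",
    sprintf("Best model: %s (dDIC = 0, pD = %s, R2 = %s)",
            rk$model[1], fmt6(rk$pD[1]), fmt6(rk$R2[1])),
    "",
    "Model ranking (ascending DIC):",
    sprintf("  %-42s pD=%8s dDIC=%8s R2=%8s%s", rk$model, fmt6(rk$pD),
            fmt6(rk$dDIC), fmt6(rk$R2),
            ifelse(rk$within_5, "  [within 5 of best]", "")),
    "",
    "Best-model posterior summary:",
    sprintf("  %-18s est=%9s sd=%9s CI95=[%s, %s]",
            bf$summary$parameter, fmt6(bf$summary$estimate),
            fmt6(bf$summary$sd), fmt6(bf$summary$q2.5),
            fmt6(bf$summary$q97.5)))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
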