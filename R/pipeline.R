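#' Pipeline run configuration
#'
#' Describes one end-to-end run: raw inputs (capture and nestling CSVs) or a
#' simulation config, the measures and analysis steps to run, state-coding
#' thresholds, and fitting options. The three steps mirror the study design:
#' `all` analyses every individual, `age` the known-age subset with
#' age-interactive parameters, `sex` the known-sex subset with
#' sex-interactive parameters.
#'
#' @param captures_csv,nestlings_csv Input paths (`nestlings_csv` is needed
#'   for the mass measure).
#' @param sim An [sim_config()] used instead of raw inputs; the simulated
#'   dataset is written into the run directory first.
#' @param measures Subset of `c("size", "mass")`.
#' @param steps Subset of `c("all", "age", "sex")`.
#' @param thresholds `"auto"` (median splits computed on the analysed
#'   dataset) or an [state_thresholds()] object to force explicit cutoffs.
#' @param smi_reference Reference tarsus length (mm) for the Scaled Mass
#'   Index; `NULL` uses the median tarsus of the nestling data.
#' @param robust_sma Use the robust SMA estimator for the allometric slope?
#' @param first_year,last_year Retained study window for the filters.
#' @param options See [fit_options()].
#' @param out_dir Output directory.
#' @return An object of class `owlcmr_runconfig`.
#' @export
run_config <- function(captures_csv = NULL, nestlings_csv = NULL, sim = NULL,
                       measures = "size", steps = "all",
                       thresholds = "auto", smi_reference = 35.1,
                       robust_sma = FALSE,
                       first_year = 2008, last_year = 2021,
                       options = fit_options(), out_dir = "owlcmr_run") {
  measures <- match.arg(measures, c("size", "mass"), several.ok = TRUE)
  steps <- match.arg(steps, c("all", "age", "sex"), several.ok = TRUE)
  if (is.null(captures_csv) && is.null(sim))
    stop("either captures_csv or sim must be given")
  structure(list(captures_csv = captures_csv, nestlings_csv = nestlings_csv,
                 sim = sim, measures = measures, steps = steps,
                 thresholds = thresholds, smi_reference = smi_reference,
                 robust_sma = robust_sma, first_year = first_year,
                 last_year = last_year, options = options, out_dir = out_dir),
            class = "owlcmr_runconfig")
}

.step_covariate <- c(all = "none", age = "age", sex = "sex")

#' Run the full analysis pipeline
#'
#' Ingest -> state coding -> model set per step and measure -> selection ->
#' report artifacts. Per measure and step the run directory receives an AIC
#' table (`aic_<measure>_<step>.tsv`), the chosen model's estimate table
#' (`estimates_<measure>_<step>.tsv`), and a JSON manifest with the resolved
#' configuration, seeds, thresholds, and per-stage counts, sufficient to
#' re-execute the run. Runs with a fixed seed are deterministic.
#'
#' @param config An [run_config()].
#' @return The run directory path, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "owlcmr_runconfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  captures_csv <- config$captures_csv
  nestlings_csv <- config$nestlings_csv
  if (!is.null(config$sim)) {
    sim <- simulate_histories(config$sim)
    paths <- write_sim_data(sim, file.path(config$out_dir, "simulated_data"))
    captures_csv <- paths[["captures"]]
    nestlings_csv <- if ("nestlings" %in% names(paths)) paths[["nestlings"]] else nestlings_csv
  }
  records <- collapse_to_annual(read_capture_records(captures_csv))
  nestlings <- if (!is.null(nestlings_csv)) read_nestlings(nestlings_csv) else NULL

  manifest <- list(measures = config$measures, steps = config$steps,
                   first_year = config$first_year, last_year = config$last_year,
                   options = config$options, seed = config$options$seed,
                   smi_reference = config$smi_reference,
                   robust_sma = config$robust_sma,
                   captures_csv = captures_csv, nestlings_csv = nestlings_csv,
                   results = list())

  for (measure in config$measures) {
    filtered <- apply_study_filters(records, config$first_year, config$last_year,
                                    require_brood_info = measure == "size")
    if (nrow(filtered) == 0L)
      stop("no records survive the study filters (years ", config$first_year,
           "-", config$last_year, ")")
    broods <- NULL; smi <- NULL
    if (measure == "mass") {
      if (is.null(nestlings)) stop("the mass measure needs a nestling CSV")
      smi <- fit_smi_params(nestlings, reference_length = config$smi_reference,
                            robust = config$robust_sma)
      broods <- brood_table(nestlings, smi)
    }
    thr <- config$thresholds
    if (identical(thr, "auto")) {
      thr <- compute_thresholds(
        brood_sizes = filtered$brood_size[filtered$breeder_with_success],
        brood_masses = if (!is.null(broods)) broods$brood_mass_g)
    }
    if (measure == "mass" && !is.null(broods))
      broods$state_mass <- ifelse(is.na(broods$brood_mass_g), "U",
                                  assign_reproductive_state(broods$brood_mass_g,
                                                            "mass", thr))
    states <- build_state_table(filtered, measure, thr, broods)
    h <- encode_histories(filtered, states, measure,
                          occasion_years = config$first_year:config$last_year)
    write_histories_csv(h, file.path(config$out_dir,
                                     paste0("histories_", measure, ".csv")))
    for (step in config$steps) {
      covariate <- .step_covariate[[step]]
      rs <- run_model_set(h, covariate = covariate, options = config$options)
      tag <- paste0(measure, "_", step)
      aic_path <- file.path(config$out_dir, paste0("aic_", tag, ".tsv"))
      tabout <- rs$table
      tabout$chosen <- ifelse(tabout$chosen, "*", "")
      write.table(format(tabout, digits = 10), aic_path, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      est_path <- file.path(config$out_dir, paste0("estimates_", tag, ".tsv"))
      best_fit <- rs$fits[[rs$selection$chosen]]
      write.table(format(best_fit$estimates, digits = 6), est_path, sep = "\t",
                  row.names = FALSE, quote = FALSE)
      manifest$results[[tag]] <- list(
        chosen = rs$selection$chosen, rule = rs$selection$rule_applied,
        n_histories = nrow(h$events), aic_table = aic_path,
        estimates = est_path,
        thresholds = list(size_low_max = thr$size_low_max,
                          mass_low_cutoff = thr$mass_low_cutoff),
        filter_counts = as.list(attr(filtered, "filter_counts")))
      message(sprintf("[%s/%s] chosen model: %s", measure, step,
                      rs$selection$chosen))
    }
  }
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             file.path(config$out_dir, "manifest.json"))
  invisible(config$out_dir)
}

#' Render a markdown report from a completed run
#'
#' One AIC table per measure x step (best model starred in bold) and the
#' chosen model's estimate summaries.
#'
#' @param run_dir Directory produced by [run_pipeline()].
#' @return Character vector of markdown lines (also written to
#'   `report.md` inside the run directory).
#' @export
render_report <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) stop("no manifest.json in ", run_dir)
  man <- jsonlite::fromJSON(man_path, simplifyVector = FALSE)
  if (length(man$results) == 0L) stop("manifest lists no results")
  missing <- character()
  out <- c("# Model selection report", "")
  for (tag in names(man$results)) {
    res <- man$results[[tag]]
    if (!file.exists(res$aic_table) || !file.exists(res$estimates)) {
      missing <- c(missing, tag); next
    }
    aic_tab <- read.delim(res$aic_table, stringsAsFactors = FALSE)
    out <- c(out, paste0("## ", gsub("_", " / ", tag)), "",
             "| Model | K | AIC | dAIC |", "|---|---|---|---|")
    for (i in seq_len(nrow(aic_tab))) {
      mod <- aic_tab$model[i]
      if (!is.na(aic_tab$chosen[i]) && aic_tab$chosen[i] == "*")
        mod <- paste0("**", mod, "**")
      aic_str <- if (is.na(aic_tab$aic[i])) "failed" else sprintf("%.2f", aic_tab$aic[i])
      d_str <- if (is.na(aic_tab$delta[i])) "" else sprintf("%.2f", aic_tab$delta[i])
      out <- c(out, sprintf("| %s | %d | %s | %s |", mod, aic_tab$K[i], aic_str, d_str))
    }
    est <- read.delim(res$estimates, stringsAsFactors = FALSE)
    out <- c(out, "", sprintf("Chosen model **%s** (%s). Estimates:", res$chosen, res$rule), "")
    out <- c(out, "| Parameter | Estimate | 95% CI |", "|---|---|---|")
    for (i in seq_len(nrow(est))) {
      ci <- if (isTRUE(est$not_estimated[i]) || is.na(est$lower[i]))
        "not estimated"
      else sprintf("[%.3f, %.3f]", est$lower[i], est$upper[i])
      out <- c(out, sprintf("| %s | %.3f | %s |", est$parameter[i],
                            est$estimate[i], ci))
    }
    out <- c(out, "")
  }
  if (length(missing))
    stop("missing artifacts for: ", paste(missing, collapse = ", "))
  writeLines(out, file.path(run_dir, "report.md"))
  out
}
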