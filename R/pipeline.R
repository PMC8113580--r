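# Configuration-driven orchestration: simulate -> process -> histfit ->
# doseresponse -> idealize -> kinetics, each stage reading the previous
# stage's outputs from disk, with a machine-readable JSON run report.

#' Build a pipeline run configuration
#'
#' All parameters are echoed verbatim into the run report. Defaults mirror
#' the package defaults of each analysis step; the generator scale defaults
#' are a compact demonstration size.
#'
#' @param kon,koff per-site rate constants (1/uM/s, 1/s).
#' @param concentrations ligand concentrations simulated (uM); 0 entries
#'   enter histograms but not the logistic abscissa.
#' @param kinetics_conc concentration whose traces are idealized and fitted.
#' @param n_movies,traces_per_movie,duration generator scale.
#' @param frame_interval camera frame time (s).
#' @param emission,photophysics [emission_params()] / [photophysics_params()].
#' @param crosstalk,gamma FRET corrections used in processing.
#' @param selection a [selection_criteria()].
#' @param bin_width histogram bin width.
#' @param n_components Gaussian components in the global fit.
#' @param dead_time dwell dead time (s).
#' @param constraint kinetic-fit constraint (`"independent_sites"` or
#'   `"free"`).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(kon = 1.0, koff = 0.46,
                       concentrations = c(0, 0.1, 0.3, 1, 3, 1000),
                       kinetics_conc = 0.3,
                       n_movies = 2, traces_per_movie = 25, duration = 40,
                       frame_interval = 0.1,
                       emission = emission_params(),
                       photophysics = photophysics_params(),
                       crosstalk = 0.105, gamma = 1.1,
                       selection = selection_criteria(),
                       bin_width = 0.02, n_components = 3,
                       dead_time = 0.2,
                       constraint = "independent_sites") {
  structure(list(kon = kon, koff = koff, concentrations = concentrations,
                 kinetics_conc = kinetics_conc, n_movies = n_movies,
                 traces_per_movie = traces_per_movie, duration = duration,
                 frame_interval = frame_interval, emission = emission,
                 photophysics = photophysics, crosstalk = crosstalk,
                 gamma = gamma, selection = selection,
                 bin_width = bin_width, n_components = n_components,
                 dead_time = dead_time, constraint = constraint),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys absent from the file keep their [run_config()] defaults.
#'
#' @param path JSON file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- run_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm == "emission") cfg$emission <- do.call(emission_params, as.list(raw[[nm]]))
    else if (nm == "photophysics") cfg$photophysics <- do.call(photophysics_params, as.list(raw[[nm]]))
    else if (nm == "selection") cfg$selection <- do.call(selection_criteria, as.list(raw[[nm]]))
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

cond_dir <- function(outdir, conc) {
  file.path(outdir, "traces", sprintf("conc_%g", conc))
}

pipeline_stages <- c("simulate", "process", "histfit", "doseresponse",
                     "idealize", "kinetics")

#' Run the analysis pipeline
#'
#' Executes the requested stages in order; each stage reads the previous
#' stage's outputs from disk under `outdir`, so stages can be re-run
#' individually. The run report (JSON, `outdir/report.json`) contains every
#' configuration parameter, selection counts, fitted state means, Gaussian
#' components, dose-response and kinetic parameters with standard errors and
#' log-likelihood, and the master seed; identical config + seed give
#' byte-identical reports.
#'
#' @param config a [run_config()].
#' @param outdir output directory.
#' @param seed master seed (integer).
#' @param stages character vector of stages, or `"all"`.
#' @return The run report, invisibly (also written to
#'   `outdir/report.json`).
#' @export
run_pipeline <- function(config, outdir, seed, stages = "all") {
  stopifnot(inherits(config, "run_config"))
  if (identical(stages, "all")) stages <- pipeline_stages
  bad <- setdiff(stages, pipeline_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report_path <- file.path(outdir, "report.json")
  report <- if (file.exists(report_path))
    jsonlite::read_json(report_path, simplifyVector = TRUE) else list()
  report$config <- serialize_config(config)
  report$seed <- seed
  report$stages_run <- union(unlist(report$stages_run), stages)

  for (stage in pipeline_stages[pipeline_stages %in% stages]) {
    t0 <- proc.time()[["elapsed"]]
    report <- switch(stage,
      simulate = stage_simulate(config, outdir, seed, report),
      process = stage_process(config, outdir, report),
      histfit = stage_histfit(config, outdir, report),
      doseresponse = stage_doseresponse(config, outdir, report),
      idealize = stage_idealize(config, outdir, report),
      kinetics = stage_kinetics(config, outdir, report))
    message(sprintf("[%s] done in %.1f s", stage,
                    proc.time()[["elapsed"]] - t0))
  }
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

serialize_config <- function(config) {
  out <- unclass(config)
  out$emission <- unclass(out$emission)
  out$photophysics <- unclass(out$photophysics)
  out$selection <- unclass(out$selection)
  out
}

stage_simulate <- function(config, outdir, seed, report) {
  for (i in seq_along(config$concentrations)) {
    conc <- config$concentrations[i]
    kp <- kinetic_params(config$kon, config$koff, conc)
    ts <- simulate_experiment(kp, config$emission, config$photophysics,
                              n_movies = config$n_movies,
                              traces_per_movie = config$traces_per_movie,
                              duration = config$duration,
                              frame_interval = config$frame_interval,
                              seed = seed + 7919L * i)
    write_trace_set(ts, cond_dir(outdir, conc))
  }
  report$n_conditions <- length(config$concentrations)
  report
}

read_condition <- function(config, outdir, conc) {
  d <- cond_dir(outdir, conc)
  if (!dir.exists(d))
    stop("stage dependency error: no simulated traces for conc ", conc,
         " under ", d, "; run the simulate stage first")
  read_trace_set(d)
}

stage_process <- function(config, outdir, report) {
  pd <- file.path(outdir, "processed")
  dir.create(pd, recursive = TRUE, showWarnings = FALSE)
  sel_counts <- list()
  for (conc in config$concentrations) {
    ts <- read_condition(config, outdir, conc)
    sel <- select_traces(ts, config$selection, config$crosstalk, config$gamma)
    rej <- attr(sel, "rejections")
    write.table(rej, file.path(pd, sprintf("rejections_conc_%g.tsv", conc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    keep <- data.frame(
      trace_id = vapply(sel$traces, `[[`, 0L, "trace_id"),
      movie_id = sel$movie_id,
      usable_frames = vapply(sel$traces, `[[`, 0L, "usable_frames"),
      acceptor_bleach_frame = vapply(sel$traces, function(t)
        as.integer(t$bleach$acceptor_bleach_frame), 0L),
      donor_bleach_frame = vapply(sel$traces, function(t)
        as.integer(t$bleach$donor_bleach_frame), 0L))
    write.table(keep, file.path(pd, sprintf("selected_conc_%g.tsv", conc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    hs <- compile_histograms(sel, bin_width = config$bin_width)
    htab <- do.call(rbind, lapply(hs, function(h)
      data.frame(movie_id = h$movie_id, bin_mid = h$mids,
                 density = h$density)))
    if (is.null(htab))
      htab <- data.frame(movie_id = integer(0), bin_mid = numeric(0),
                         density = numeric(0))
    write.table(htab, file.path(pd, sprintf("histograms_conc_%g.tsv", conc)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    sel_counts[[sprintf("conc_%g", conc)]] <-
      list(selected = length(sel$traces),
           rejected = nrow(rej))
  }
  report$selection <- sel_counts
  report
}

read_histograms <- function(config, outdir, conc) {
  f <- file.path(outdir, "processed", sprintf("histograms_conc_%g.tsv", conc))
  if (!file.exists(f))
    stop("stage dependency error: ", f, " missing; run the process stage")
  tab <- read.table(f, header = TRUE, sep = "\t")
  breaks <- default_fret_breaks(config$bin_width)
  lapply(split(tab, tab$movie_id), function(sub) {
    new_fret_histogram(breaks, sub$density[order(sub$bin_mid)],
                       n_molecules = NA, movie_id = sub$movie_id[1],
                       condition = list(conc = conc))
  })
}

stage_histfit <- function(config, outdir, report) {
  hs <- list()
  for (conc in config$concentrations)
    hs <- c(hs, read_histograms(config, outdir, conc))
  gf <- global_fit(hs, k = config$n_components)
  area_tab <- data.frame(conc = gf$conc, gf$areas)
  write.table(area_tab, file.path(outdir, "processed", "global_areas.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$state_means <- gf$components$mean
  report$state_sds <- gf$components$sd
  report$global_fit_ssr <- gf$ssr
  report
}

stage_doseresponse <- function(config, outdir, report) {
  f <- file.path(outdir, "processed", "global_areas.tsv")
  if (!file.exists(f))
    stop("stage dependency error: ", f, " missing; run the histfit stage")
  tab <- read.table(f, header = TRUE, sep = "\t")
  agg <- stats::aggregate(low ~ conc, tab, mean)
  fit <- fit_dose_response(agg$conc, agg$low)
  report$ec50 <- fit$ec50
  report$hill <- fit$hill
  report$fmax <- fit$fmax
  report$dose_response_se <- as.list(fit$se)
  report
}

stage_idealize <- function(config, outdir, report) {
  conc <- config$kinetics_conc
  ts <- read_condition(config, outdir, conc)
  sel <- select_traces(ts, config$selection, config$crosstalk, config$gamma)
  xs <- idealization_input(sel)
  fit <- skm_idealize(xs, n_states = 3)
  dwell_rows <- list()
  for (i in seq_along(fit$traces)) {
    it <- remove_zero_state(fit$traces[[i]])
    if (isTRUE(attr(it, "empty"))) next
    ds <- extract_dwells(it, config$dead_time)
    if (nrow(ds) > 0)
      dwell_rows[[length(dwell_rows) + 1]] <-
        data.frame(trace = i, state = ds$state, duration = ds$duration)
  }
  dtab <- do.call(rbind, dwell_rows)
  write.table(dtab, file.path(outdir, "processed",
                              sprintf("dwells_conc_%g.tsv", conc)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$skm_state_means <- fit$state_means
  report$skm_state_sds <- fit$state_sds
  report$n_dwells <- if (is.null(dtab)) 0L else nrow(dtab)
  report
}

stage_kinetics <- function(config, outdir, report) {
  conc <- config$kinetics_conc
  f <- file.path(outdir, "processed", sprintf("dwells_conc_%g.tsv", conc))
  if (!file.exists(f))
    stop("stage dependency error: ", f, " missing; run the idealize stage")
  dtab <- read.table(f, header = TRUE, sep = "\t")
  ds <- lapply(split(dtab, dtab$trace), function(sub) {
    structure(data.frame(state = sub$state, duration = sub$duration,
                         start_frame = NA_integer_, end_frame = NA_integer_),
              dead_time = config$dead_time,
              frame_interval = config$frame_interval,
              censored_first = TRUE, censored_last = TRUE,
              class = c("dwell_sequence", "data.frame"))
  })
  scheme <- scheme_spec("linear", config$constraint, conc = conc)
  fit <- fit_rates(ds, scheme, dead_time = config$dead_time)
  report$rates <- as.list(fit$rates)
  report$rate_se <- as.list(fit$se)
  report$loglik <- fit$loglik
  report$kd <- fit$kd
  report$kd_se <- fit$kd_se
  report$kinetics_converged <- fit$converged
  report
}
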