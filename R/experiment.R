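# Simulated experiments: movies of independent traces under one condition.

# Deterministic per-trace seed from the master seed and a trace counter, so
# any subset of traces is reproducible independently of the others.
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 1009 + 12345) %% 2147483647)
}

#' Simulate a set of smFRET movies under one condition
#'
#' Generates `n_movies * traces_per_movie` independent traces from the
#' two-site binding scheme: each trace is a Gillespie state path started from
#' the equilibrium distribution at the given concentration, rendered to
#' donor/acceptor intensities with noise and photobleaching.
#'
#' @param kp a [kinetic_params()] object (concentration taken from it).
#' @param em an [emission_params()] object.
#' @param ph a [photophysics_params()] object.
#' @param n_movies number of movies (>= 1).
#' @param traces_per_movie traces per movie (>= 1).
#' @param duration trace duration (s).
#' @param frame_interval camera frame time (s).
#' @param seed master seed; every trace derives its own seed from it.
#' @param condition optional named list of condition labels (e.g. ligands,
#'   pH); the concentration is always recorded.
#' @param bad_fraction fraction of traces rendered with selection-defeating
#'   artifacts (two-step acceptor or drifting total), default 0.
#' @return An object of class `trace_set`: list with `traces` (list of
#'   `photon_trace`, each carrying `movie_id` and `trace_id`), `movie_id`
#'   vector, `condition`, `frame_interval`, `seed` and the generator
#'   parameters.
#' @export
simulate_experiment <- function(kp, em = emission_params(),
                                ph = photophysics_params(),
                                n_movies = 5, traces_per_movie = 120,
                                duration = 60, frame_interval = 0.1,
                                seed = 1, condition = list(),
                                bad_fraction = 0) {
  stopifnot(inherits(kp, "kinetic_params"))
  if (n_movies < 1 || traces_per_movie < 1)
    stop("n_movies and traces_per_movie must be >= 1")
  Q <- build_rate_matrix(kp)
  n <- n_movies * traces_per_movie
  movie_id <- rep(seq_len(n_movies), each = traces_per_movie)
  traces <- vector("list", n)
  for (i in seq_len(n)) {
    si <- derive_seed(seed, i)
    set.seed(si)
    path <- simulate_state_path(Q, duration, start_state = "stationary")
    artifacts <- NULL
    if (bad_fraction > 0 && runif(1) < bad_fraction) {
      if (runif(1) < 0.5) {
        artifacts <- list(extra_acceptor_step = runif(1, 5, duration / 2))
      } else {
        artifacts <- list(drift_rate = 0.02 * sample(c(-1, 1), 1))
      }
    }
    tr <- render_trace(path, em, ph, frame_interval, artifacts = artifacts)
    tr$movie_id <- movie_id[i]
    tr$trace_id <- i
    traces[[i]] <- tr
  }
  condition$conc <- kp$conc
  structure(list(traces = traces, movie_id = movie_id,
                 condition = condition, frame_interval = frame_interval,
                 seed = seed,
                 params = list(kinetics = kp, emission = em, photophysics = ph,
                               n_movies = n_movies,
                               traces_per_movie = traces_per_movie,
                               duration = duration)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d traces in %d movies, conc = %.4g uM, %.3g s/frame, seed %d\n",
              length(x$traces), length(unique(x$movie_id)),
              x$condition$conc, x$frame_interval, x$seed))
  invisible(x)
}

#' Write a trace set to disk
#'
#' One TSV per movie (columns `trace_id`, `frame_index`, `donor`,
#' `acceptor`) plus a JSON metadata sidecar (`metadata.json`) holding the
#' condition, frame interval, seed and generator parameters.
#'
#' @param ts a `trace_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_trace_set <- function(ts, dir) {
  stopifnot(inherits(ts, "trace_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in sort(unique(ts$movie_id))) {
    idx <- which(ts$movie_id == m)
    tab <- do.call(rbind, lapply(idx, function(i) {
      tr <- ts$traces[[i]]
      data.frame(trace_id = tr$trace_id,
                 frame_index = seq_along(tr$donor),
                 donor = tr$donor, acceptor = tr$acceptor)
    }))
    write.table(tab, file.path(dir, sprintf("movie_%03d.tsv", m)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  kp <- ts$params$kinetics
  meta <- list(condition = ts$condition,
               frame_interval = ts$frame_interval,
               seed = ts$seed,
               n_movies = ts$params$n_movies,
               traces_per_movie = ts$params$traces_per_movie,
               duration = ts$params$duration,
               kinetics = if (!is.null(kp)) list(kon = kp$kon, koff = kp$koff,
                                                 conc = kp$conc),
               emission = unclass(ts$params$emission),
               photophysics = unclass(ts$params$photophysics))
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a trace set written by [write_trace_set()]
#'
#' @param dir directory containing `movie_*.tsv` and `metadata.json`.
#' @return A `trace_set` (without generator truth records).
#' @export
read_trace_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^movie_\\d+\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no movie_*.tsv files in ", dir)
  traces <- list(); movie_id <- integer(0)
  for (f in files) {
    m <- as.integer(sub("^movie_0*(\\d+)\\.tsv$", "\\1", basename(f)))
    tab <- read.table(f, header = TRUE, sep = "\t")
    for (id in unique(tab$trace_id)) {
      sub <- tab[tab$trace_id == id, ]
      sub <- sub[order(sub$frame_index), ]
      tr <- structure(list(donor = sub$donor, acceptor = sub$acceptor,
                           frame_interval = meta$frame_interval,
                           movie_id = m, trace_id = id),
                      class = "photon_trace")
      traces[[length(traces) + 1]] <- tr
      movie_id <- c(movie_id, m)
    }
  }
  structure(list(traces = traces, movie_id = movie_id,
                 condition = as.list(meta$condition),
                 frame_interval = meta$frame_interval,
                 seed = meta$seed,
                 params = list(n_movies = meta$n_movies,
                               traces_per_movie = meta$traces_per_movie,
                               duration = meta$duration)),
            class = "trace_set")
}
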