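# Per-movie normalized FRET histograms and their across-movie aggregation.

default_fret_breaks <- function(bin_width = 0.02) {
  seq(-0.2, 1.2, by = bin_width)
}

new_fret_histogram <- function(breaks, density, n_molecules, movie_id = NA,
                               condition = list(), sem = NULL,
                               n_movies = 1L) {
  structure(list(breaks = breaks,
                 mids = (head(breaks, -1) + tail(breaks, -1)) / 2,
                 density = density, sem = sem,
                 n_molecules = n_molecules, movie_id = movie_id,
                 n_movies = n_movies, condition = condition),
            class = "fret_histogram")
}

#' Compile per-movie normalized FRET histograms
#'
#' For every movie, pools the first `window` seconds of usable FRET (frames
#' before the first bleaching event) from all selected traces and bins them
#' on a fixed grid; each movie's histogram is normalized to integrate to 1
#' before any aggregation. Frames after acceptor bleach never enter (the
#' usable range ends at the first bleach).
#'
#' @param ts a selected `trace_set` (see [select_traces()]); an unselected
#'   set is selected first with default criteria.
#' @param window seconds of trace used from the start (default 20).
#' @param bin_width histogram bin width in FRET units (default 0.02); bins
#'   span -0.2 to 1.2; values outside are dropped.
#' @param crosstalk,gamma FRET correction parameters (defaults taken from
#'   the selection record when present).
#' @return List of `fret_histogram`, one per movie with at least one
#'   selected trace (movies with none are dropped with a warning).
#' @export
compile_histograms <- function(ts, window = 20, bin_width = 0.02,
                               crosstalk = NULL, gamma = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(attr(ts, "selected"))) ts <- select_traces(ts)
  if (is.null(crosstalk)) crosstalk <- if (!is.null(ts$crosstalk)) ts$crosstalk else 0.105
  if (is.null(gamma)) gamma <- if (!is.null(ts$gamma)) ts$gamma else 1.1
  breaks <- default_fret_breaks(bin_width)
  movies <- sort(unique(ts$movie_id))
  out <- list()
  for (m in movies) {
    idx <- which(ts$movie_id == m)
    vals <- numeric(0)
    for (i in idx) {
      tr <- ts$traces[[i]]
      ft <- compute_fret(tr, crosstalk, gamma)
      nf <- min(tr$usable_frames, floor(window / tr$frame_interval + 1e-9))
      v <- ft$fret[seq_len(nf)]
      vals <- c(vals, v[is.finite(v)])
    }
    vals <- vals[vals >= breaks[1] & vals < breaks[length(breaks)]]
    if (length(vals) == 0) {
      warning(sprintf("movie %s has no usable frames; excluded", m))
      next
    }
    counts <- tabulate(findInterval(vals, breaks), nbins = length(breaks) - 1)
    density <- counts / (sum(counts) * bin_width)
    out[[length(out) + 1]] <-
      new_fret_histogram(breaks, density, n_molecules = length(idx),
                         movie_id = m, condition = ts$condition)
  }
  if (length(out) == 0) warning("no movie yielded a histogram")
  out
}

#' Aggregate per-movie histograms into a mean histogram with SEM
#'
#' Bin-wise mean and standard error of the mean across movies; per-movie
#' normalization has already happened in [compile_histograms()].
#'
#' @param histograms list of `fret_histogram` with identical breaks.
#' @return A single `fret_histogram` with `sem` filled in, `n_movies` set,
#'   and `n_molecules` summed.
#' @export
aggregate_histograms <- function(histograms) {
  stopifnot(length(histograms) >= 1,
            all(vapply(histograms, inherits, TRUE, "fret_histogram")))
  b <- histograms[[1]]$breaks
  for (h in histograms)
    if (!isTRUE(all.equal(h$breaks, b))) stop("histograms have differing bins")
  dm <- do.call(rbind, lapply(histograms, `[[`, "density"))
  n <- nrow(dm)
  mean_d <- colMeans(dm)
  sem <- if (n > 1) apply(dm, 2, stats::sd) / sqrt(n) else rep(0, ncol(dm))
  new_fret_histogram(b, mean_d,
                     n_molecules = sum(vapply(histograms, `[[`, 0, "n_molecules")),
                     movie_id = NA, condition = histograms[[1]]$condition,
                     sem = sem, n_movies = n)
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat(sprintf("fret_histogram: %d bins [%g, %g], %d molecules, %s\n",
              length(x$density), min(x$breaks), max(x$breaks),
              x$n_molecules,
              if (is.na(x$movie_id)) sprintf("aggregate of %d movies", x$n_movies)
              else sprintf("movie %s", x$movie_id)))
  invisible(x)
}

#' Plot a FRET histogram
#'
#' @param x a `fret_histogram`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fret_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "s", xlab = "FRET",
                 ylab = "Probability density", ...)
  if (!is.null(x$sem))
    graphics::arrows(x$mids, x$density - x$sem, x$mids, x$density + x$sem,
                     length = 0.02, angle = 90, code = 3, col = "grey50")
  invisible(x)
}
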