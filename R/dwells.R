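# Dwell sequences with dead-time merging, and transition-density plots.

label_runs <- function(labels) {
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values, n = r$lengths,
             start_frame = ends - r$lengths + 1L, end_frame = ends)
}

#' Extract a dead-time-merged dwell sequence from an idealized trace
#'
#' Converts label runs to (state, duration) dwells and merges any dwell
#' shorter than the dead time into its preceding dwell (duration added; a
#' short first dwell merges into the following one), iterating until every
#' dwell is at least the dead time long. Adjacent dwells that end up in the
#' same state coalesce, so total idealized time is conserved. First and last
#' dwells are flagged censored (their start/end is set by the observation
#' window, not by a transition).
#'
#' @param it an `idealized_trace` without zero-state frames (see
#'   [remove_zero_state()]).
#' @param dead_time shortest resolvable dwell (s), default 0.2.
#' @return An object of class `dwell_sequence`: data.frame with columns
#'   `state`, `duration` (s), `start_frame`, `end_frame`; attributes
#'   `dead_time`, `frame_interval`, `censored_first`, `censored_last`. A
#'   trace shorter than the dead time yields an empty sequence flagged with
#'   `attr(, "empty")`.
#' @export
extract_dwells <- function(it, dead_time = 0.2) {
  stopifnot(inherits(it, "idealized_trace"))
  if (any(it$labels == 0))
    stop("remove the zero-FRET state before extracting dwells")
  dt <- it$frame_interval
  runs <- label_runs(it$labels)
  runs$duration <- runs$n * dt
  if (nrow(runs) == 0 || sum(runs$duration) < dead_time) {
    out <- structure(data.frame(state = integer(0), duration = numeric(0),
                                start_frame = integer(0),
                                end_frame = integer(0)),
                     dead_time = dead_time, frame_interval = dt,
                     censored_first = TRUE, censored_last = TRUE,
                     class = c("dwell_sequence", "data.frame"))
    attr(out, "empty") <- TRUE
    return(out)
  }
  repeat {
    short <- which(runs$duration < dead_time - 1e-12)
    if (length(short) == 0) break
    i <- short[1]
    if (i == 1) {
      if (nrow(runs) == 1) break     # single short dwell: handled above
      runs$duration[2] <- runs$duration[2] + runs$duration[1]
      runs$start_frame[2] <- runs$start_frame[1]
      runs <- runs[-1, , drop = FALSE]
    } else {
      runs$duration[i - 1] <- runs$duration[i - 1] + runs$duration[i]
      runs$end_frame[i - 1] <- runs$end_frame[i]
      runs <- runs[-i, , drop = FALSE]
    }
    # coalesce adjacent equal states
    j <- 1
    while (j < nrow(runs)) {
      if (runs$state[j] == runs$state[j + 1]) {
        runs$duration[j] <- runs$duration[j] + runs$duration[j + 1]
        runs$end_frame[j] <- runs$end_frame[j + 1]
        runs <- runs[-(j + 1), , drop = FALSE]
      } else j <- j + 1
    }
  }
  rownames(runs) <- NULL
  structure(runs[, c("state", "duration", "start_frame", "end_frame")],
            dead_time = dead_time, frame_interval = dt,
            censored_first = TRUE, censored_last = TRUE,
            class = c("dwell_sequence", "data.frame"))
}

#' Transition-density plot data from idealized traces
#'
#' One count per transition at (mean FRET of the preceding dwell, mean FRET
#' of the following dwell), accumulated over traces on a 2-D grid, with the
#' average number of transitions per second (`t_per_s`) and the total
#' transition count (`n_transitions`). Dwells are taken after dead-time
#' merging when `dead_time > 0`, so the counts equal the number of dwells
#' minus the number of traces.
#'
#' @param its list of `idealized_trace` (zero-state frames already removed),
#'   or a `skm_fit`.
#' @param dead_time dead time for dwell merging (s); 0 uses raw label runs.
#' @param breaks grid breaks for both FRET axes.
#' @return An object of class `transition_density`: `grid` (counts,
#'   before x after), `breaks`, `n_transitions`, `t_per_s`, `pairs`
#'   (data.frame of before/after FRET and state per transition).
#' @export
transition_density <- function(its, dead_time = 0,
                               breaks = seq(-0.2, 1.2, by = 0.02)) {
  if (inherits(its, "skm_fit")) its <- its$traces
  if (inherits(its, "idealized_trace")) its <- list(its)
  stopifnot(all(vapply(its, inherits, TRUE, "idealized_trace")))
  before <- numeric(0); after <- numeric(0)
  s_before <- integer(0); s_after <- integer(0)
  total_time <- 0
  for (it in its) {
    ds <- extract_dwells(it, dead_time)
    total_time <- total_time + sum(ds$duration)
    if (nrow(ds) < 2) next
    fr <- vapply(seq_len(nrow(ds)), function(i)
      mean(it$x[ds$start_frame[i]:ds$end_frame[i]]), 0)
    idx <- seq_len(nrow(ds) - 1)
    before <- c(before, fr[idx]); after <- c(after, fr[idx + 1])
    s_before <- c(s_before, ds$state[idx]); s_after <- c(s_after, ds$state[idx + 1])
  }
  nb <- length(breaks) - 1
  grid <- matrix(0L, nb, nb)
  if (length(before) > 0) {
    bi <- findInterval(before, breaks, rightmost.closed = TRUE)
    ai <- findInterval(after, breaks, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= nb & ai >= 1 & ai <= nb
    for (i in which(ok)) grid[bi[i], ai[i]] <- grid[bi[i], ai[i]] + 1L
  }
  structure(list(grid = grid, breaks = breaks,
                 n_transitions = length(before),
                 t_per_s = if (total_time > 0) length(before) / total_time else 0,
                 total_time = total_time,
                 pairs = data.frame(before = before, after = after,
                                    state_before = s_before,
                                    state_after = s_after)),
            class = "transition_density")
}

#' Fraction of direct transitions between the outermost states
#'
#' Among all idealized transitions, the fraction jumping directly between
#' the highest- and lowest-FRET conformational states (skipping the middle
#' state). Under the linear binding scheme this should be close to zero.
#'
#' @param td a `transition_density`.
#' @param high,low state labels of the outermost states.
#' @return A single fraction (0 when there are no transitions).
#' @export
direct_transition_fraction <- function(td, high = 1L, low = 3L) {
  stopifnot(inherits(td, "transition_density"))
  p <- td$pairs
  if (nrow(p) == 0) return(0)
  direct <- (p$state_before == high & p$state_after == low) |
    (p$state_before == low & p$state_after == high)
  mean(direct)
}

#' @export
print.transition_density <- function(x, ...) {
  cat(sprintf("transition_density: N_t = %d, t/s = %.3g over %.4g s\n",
              x$n_transitions, x$t_per_s, x$total_time))
  invisible(x)
}

#' Plot a transition-density map
#'
#' @param x a `transition_density`.
#' @param ... passed to [graphics::image()].
#' @export
plot.transition_density <- function(x, ...) {
  mids <- (head(x$breaks, -1) + tail(x$breaks, -1)) / 2
  graphics::image(mids, mids, x$grid, xlab = "FRET before",
                  ylab = "FRET after", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Dwell-time histogram with logarithmic (Sigworth-Sine style) binning
#'
#' Convenience summary of dwell durations per state for plotting; kinetic
#' fitting always uses the raw dwells, never binned ones.
#'
#' @param ds_list list of `dwell_sequence`.
#' @param state state label to summarize.
#' @param n_bins number of logarithmic bins.
#' @param log_binning logarithmic (default) or linear binning.
#' @return data.frame with `mid`, `count`, `density`.
#' @export
dwell_histogram <- function(ds_list, state, n_bins = 20, log_binning = TRUE) {
  if (inherits(ds_list, "dwell_sequence")) ds_list <- list(ds_list)
  d <- unlist(lapply(ds_list, function(ds) ds$duration[ds$state == state]))
  if (length(d) == 0)
    return(data.frame(mid = numeric(0), count = integer(0),
                      density = numeric(0)))
  if (log_binning) {
    br <- exp(seq(log(min(d) * 0.999), log(max(d) * 1.001),
                  length.out = n_bins + 1))
  } else {
    br <- seq(min(d) * 0.999, max(d) * 1.001, length.out = n_bins + 1)
  }
  ct <- tabulate(findInterval(d, br, rightmost.closed = TRUE), nbins = n_bins)
  data.frame(mid = (head(br, -1) + tail(br, -1)) / 2, count = ct,
             density = ct / (sum(ct) * diff(br)))
}
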