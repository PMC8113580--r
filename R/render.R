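# Forward model: state path -> donor/acceptor intensity trace.
#
# The rendering deliberately inverts the analysis-side corrections: corrected
# intensities are constructed so that compute_fret() with the same crosstalk
# and gamma recovers the frame-averaged state FRET exactly at zero noise.

# Time-weighted mean of state means over each camera frame (motion blur at
# the frame integration time). Returns a numeric vector of length n_frames.
frame_average_fret <- function(path, state_means, frame_interval, n_frames) {
  means <- state_means[path$state]
  # cumulative integral of the piecewise-constant mean at segment knots
  knots <- c(path$start[1], path$end)
  cum <- c(0, cumsum(means * (path$end - path$start)))
  edges <- seq(0, by = frame_interval, length.out = n_frames + 1)
  edges <- pmin(edges, knots[length(knots)])
  ci <- approx(knots, cum, xout = edges, rule = 2)$y
  diff(ci) / frame_interval
}

# Ideal corrected-total -> raw channel intensities for a given FRET value.
# With IDc = gamma * ID and T = IDc + IA:
#   IA  = T (E + ct) / (1 + ct);  IDc = T (1 - E) / (1 + ct)
fret_to_channels <- function(E, total, crosstalk, gamma) {
  IA <- total * (E + crosstalk) / (1 + crosstalk)
  ID <- total * (1 - E) / (1 + crosstalk) / gamma
  list(donor = ID, acceptor = IA)
}

#' Render a donor/acceptor intensity trace from a state path
#'
#' Per frame, the true FRET is the time-weighted average of the state FRET
#' means within the frame. Ideal corrected intensities are constructed so
#' that [compute_fret()] with the same crosstalk and gamma recovers the true
#' FRET exactly at zero noise; additive Gaussian noise is then applied per
#' channel. Donor and acceptor bleach times are drawn exponentially: after
#' acceptor bleach the rendered FRET is ~0 with the donor persisting, after
#' donor bleach both channels fall to the background level.
#'
#' @param path a [simulate_state_path()] result covering the trace duration.
#' @param em an [emission_params()] object.
#' @param ph a [photophysics_params()] object.
#' @param frame_interval camera frame time (s), default 0.1.
#' @param seed optional integer seed.
#' @param bleach_times optional list with elements `donor` and `acceptor`
#'   (s) overriding the random draw; use `Inf` for no bleaching.
#' @param artifacts optional list describing deliberately "bad" traces for
#'   exercising the selection filter: `extra_acceptor_step` (time in s at
#'   which the acceptor loses half its remaining signal, emulating a second
#'   fluorophore) and/or `drift_rate` (fractional linear drift of the total
#'   intensity per second).
#' @return An object of class `photon_trace`: list with `donor`, `acceptor`,
#'   `frame_interval`, and a `truth` record (true per-frame FRET, bleach
#'   times, the state path).
#' @export
render_trace <- function(path, em, ph, frame_interval = 0.1, seed = NULL,
                         bleach_times = NULL, artifacts = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(em, "emission_params"),
            inherits(ph, "photophysics_params"))
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  if (!is.null(seed)) set.seed(seed)
  duration <- attr(path, "duration")
  n_frames <- floor(duration / frame_interval + 1e-9)
  if (n_frames < 1) stop("path shorter than one frame")

  E_true <- frame_average_fret(path, em$state_means, frame_interval, n_frames)

  if (is.null(bleach_times)) {
    t_don <- rexp(1, 1 / ph$donor_bleach_mean)
    t_acc <- rexp(1, 1 / ph$acceptor_bleach_mean)
  } else {
    t_don <- bleach_times$donor
    t_acc <- bleach_times$acceptor
  }

  frame_start <- (seq_len(n_frames) - 1) * frame_interval
  acc_gone <- frame_start >= t_acc
  don_gone <- frame_start >= t_don

  E_render <- E_true
  E_render[acc_gone] <- 0
  ch <- fret_to_channels(E_render, em$total_intensity, em$crosstalk, em$gamma)
  donor <- ch$donor
  acceptor <- ch$acceptor

  if (!is.null(artifacts$extra_acceptor_step)) {
    k <- frame_start >= artifacts$extra_acceptor_step
    acceptor[k] <- acceptor[k] / 2
  }
  if (!is.null(artifacts$drift_rate)) {
    f <- 1 + artifacts$drift_rate * frame_start
    donor <- donor * f
    acceptor <- acceptor * f
  }

  donor[don_gone] <- ph$background_level
  acceptor[don_gone] <- ph$background_level

  if (em$noise_sd > 0) {
    donor <- donor + rnorm(n_frames, 0, em$noise_sd)
    acceptor <- acceptor + rnorm(n_frames, 0, em$noise_sd)
  }

  structure(list(donor = donor, acceptor = acceptor,
                 frame_interval = frame_interval,
                 truth = list(fret = E_true,
                              donor_bleach_time = t_don,
                              acceptor_bleach_time = t_acc,
                              path = path)),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("photon_trace: %d frames at %.3g s/frame\n",
              length(x$donor), x$frame_interval))
  invisible(x)
}
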