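# Photobleaching detection by exhaustive single-change-point scans and
# recursive binary segmentation.

#' Locate the best single change point in a signal
#'
#' Exhaustive scan over split positions: the returned split maximizes the
#' between-segment mean difference normalized by the pooled within-segment
#' standard deviation (a two-sample t statistic). A noiseless step yields an
#' infinite statistic.
#'
#' @param x numeric vector.
#' @param min_seg minimum frames per segment.
#' @return List with `frame` (last frame of the left segment), `tstat`,
#'   `drop` (left mean minus right mean) and the two segment means, or
#'   `NULL` if `x` is too short.
#' @export
find_change_point <- function(x, min_seg = 5) {
  n <- length(x)
  if (n < 2 * min_seg) return(NULL)
  ks <- min_seg:(n - min_seg)
  cs <- cumsum(x); css <- cumsum(x^2)
  n1 <- ks; n2 <- n - ks
  m1 <- cs[ks] / n1
  m2 <- (cs[n] - cs[ks]) / n2
  ss1 <- pmax(css[ks] - n1 * m1^2, 0)          # guard cancellation
  ss2 <- pmax((css[n] - css[ks]) - n2 * m2^2, 0)
  sp2 <- (ss1 + ss2) / pmax(n - 2, 1)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tt <- ifelse(se > 0, abs(m1 - m2) / se,
               ifelse(abs(m1 - m2) > 0, Inf, 0))
  i <- which.max(tt)
  list(frame = ks[i], tstat = tt[i], drop = m1[i] - m2[i],
       mean_left = m1[i], mean_right = m2[i])
}

# Recursive binary segmentation: returns data.frame of significant change
# points (frame, drop, tstat, mean_left, mean_right), ordered by frame.
find_steps <- function(x, threshold = 8, min_seg = 5, offset = 0, depth = 8) {
  if (depth <= 0 || length(x) < 2 * min_seg) {
    return(data.frame(frame = integer(0), drop = numeric(0),
                      tstat = numeric(0), mean_left = numeric(0),
                      mean_right = numeric(0)))
  }
  cp <- find_change_point(x, min_seg)
  if (is.null(cp) || cp$tstat < threshold) {
    return(data.frame(frame = integer(0), drop = numeric(0),
                      tstat = numeric(0), mean_left = numeric(0),
                      mean_right = numeric(0)))
  }
  k <- cp$frame
  left <- find_steps(x[seq_len(k)], threshold, min_seg, offset, depth - 1)
  right <- find_steps(x[(k + 1):length(x)], threshold, min_seg,
                      offset + k, depth - 1)
  here <- data.frame(frame = offset + k, drop = cp$drop, tstat = cp$tstat,
                     mean_left = cp$mean_left, mean_right = cp$mean_right)
  out <- rbind(left, here, right)
  out[order(out$frame), , drop = FALSE]
}

# A detected change point counts as a fluorophore bleach/loss step when the
# signal falls to below `step_frac` of its local pre-step level. FRET
# transitions move at most ~30% of a channel and are not counted; losing a
# fluorophore at least halves it.
is_bleach_step <- function(steps, step_frac = 0.6) {
  if (nrow(steps) == 0) return(logical(0))
  steps$drop > 0 & steps$mean_right < step_frac * steps$mean_left + 1e-12
}

#' Detect donor and acceptor photobleaching events in a trace
#'
#' Donor bleaching is located on the total (donor + acceptor) intensity,
#' which is insensitive to FRET transitions; acceptor bleaching on the
#' acceptor channel restricted to frames before the donor bleach. Change
#' points come from recursive exhaustive scans; a change point counts as a
#' bleach step only when the signal falls below `step_frac` of its pre-step
#' level, so conformational FRET shifts are not mistaken for bleaching while
#' the half-drops of a doubly labeled molecule are.
#'
#' @param trace a `photon_trace`.
#' @param threshold minimum change-point t statistic.
#' @param step_frac maximal post/pre mean ratio for a bleach step.
#' @param min_seg minimum frames per scan segment.
#' @return List with `donor_bleach_frame` and `acceptor_bleach_frame` (first
#'   frame after the step; `NA` if none), `donor_steps` and
#'   `acceptor_steps` (counts), and `first_bleach_frame` (first frame lost
#'   to either event; `n + 1` if none).
#' @export
detect_bleach_events <- function(trace, threshold = 8, step_frac = 0.6,
                                 min_seg = 5) {
  n <- length(trace$donor)
  if (n < 10) stop("trace must have at least 10 frames")
  total <- trace$donor + trace$acceptor

  tot_steps <- find_steps(total, threshold, min_seg)
  tot_bleach <- tot_steps[is_bleach_step(tot_steps, step_frac), , drop = FALSE]
  donor_steps <- nrow(tot_bleach)
  donor_frame <- if (donor_steps > 0) tot_bleach$frame[1] + 1L else NA_integer_

  acc_end <- if (is.na(donor_frame)) n else donor_frame - 1L
  if (acc_end >= 2 * min_seg) {
    acc_steps_df <- find_steps(trace$acceptor[seq_len(acc_end)],
                               threshold, min_seg)
    acc_bleach <- acc_steps_df[is_bleach_step(acc_steps_df, step_frac), ,
                               drop = FALSE]
  } else {
    acc_bleach <- data.frame(frame = integer(0))
  }
  acceptor_steps <- nrow(acc_bleach)
  acceptor_frame <- if (acceptor_steps > 0) acc_bleach$frame[1] + 1L else NA_integer_

  first <- min(c(donor_frame, acceptor_frame, n + 1L), na.rm = TRUE)
  list(donor_bleach_frame = donor_frame,
       acceptor_bleach_frame = acceptor_frame,
       donor_steps = donor_steps,
       acceptor_steps = acceptor_steps,
       first_bleach_frame = as.integer(first))
}
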