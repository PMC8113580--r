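#' Apply molecule-selection criteria to a trace set
#'
#' Retains traces showing single-step donor photobleaching, no multi-step
#' acceptor photobleaching, a stable total intensity (coefficient of
#' variation below threshold over the usable range) and at least
#' `min_duration` seconds of FRET before the first bleaching event. Every
#' rejection carries a reason code. Selection is idempotent.
#'
#' @param ts a `trace_set`.
#' @param crit a [selection_criteria()] object.
#' @param crosstalk,gamma correction parameters forwarded to downstream
#'   processing and recorded on the result.
#' @return A `trace_set` containing the surviving traces, each annotated
#'   with its bleach record (`$bleach`) and usable frame count
#'   (`$usable_frames`); attribute `rejections` is a data.frame of
#'   `trace_id`, `movie_id`, `reason` for the discarded traces.
#' @export
select_traces <- function(ts, crit = selection_criteria(),
                          crosstalk = 0.105, gamma = 1.1) {
  stopifnot(inherits(ts, "trace_set"), inherits(crit, "selection_criteria"))
  keep <- logical(length(ts$traces))
  reasons <- character(0); rid <- integer(0); rmov <- integer(0)
  for (i in seq_along(ts$traces)) {
    tr <- ts$traces[[i]]
    ev <- tr$bleach
    if (is.null(ev)) ev <- detect_bleach_events(tr)
    usable <- ev$first_bleach_frame - 1L
    reason <- NULL
    if (crit$require_single_donor_bleach && ev$donor_steps == 0) {
      reason <- "no_donor_bleach"
    } else if (ev$donor_steps > 1) {
      reason <- "multi_step_donor"
    } else if (crit$require_single_acceptor_bleach && ev$acceptor_steps > 1) {
      reason <- "multi_step_acceptor"
    } else if (usable * tr$frame_interval < crit$min_duration) {
      reason <- "too_short"
    } else {
      tot <- tr$donor[seq_len(usable)] + tr$acceptor[seq_len(usable)]
      cv <- stats::sd(tot) / abs(mean(tot))
      if (!is.finite(cv) || cv > crit$total_stability_cv_max)
        reason <- "unstable_total"
    }
    if (is.null(reason)) {
      keep[i] <- TRUE
      tr$bleach <- ev
      tr$usable_frames <- usable
      ts$traces[[i]] <- tr
    } else {
      reasons <- c(reasons, reason)
      rid <- c(rid, if (!is.null(tr$trace_id)) tr$trace_id else i)
      rmov <- c(rmov, if (!is.null(tr$movie_id)) tr$movie_id else NA_integer_)
    }
  }
  out <- ts
  out$traces <- ts$traces[keep]
  out$movie_id <- ts$movie_id[keep]
  out$crosstalk <- crosstalk
  out$gamma <- gamma
  attr(out, "rejections") <- data.frame(trace_id = rid, movie_id = rmov,
                                        reason = reasons)
  attr(out, "selected") <- TRUE
  out
}
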