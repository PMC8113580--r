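# Independent oracles used by the property tests. These deliberately avoid
# the package's own code paths.

# Exhaustive-enumeration Viterbi: score every possible labeling.
oracle_best_path <- function(x, means, sds, logA, logpi) {
  K <- length(means)
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  scores <- apply(paths, 1, function(p) {
    s <- logpi[p[1]] + sum(dnorm(x, means[p], sds[p], log = TRUE))
    if (n > 1) s <- s + sum(logA[cbind(p[-n], p[-1])])
    s
  })
  i <- which.max(scores)
  list(score = scores[i], path = unname(paths[i, ]))
}

# Recursive dead-time merge: first sub-dead-time dwell merges into its
# preceding dwell (into the following one if it is first), equal-state
# neighbors coalesce, repeat until stable.
oracle_merge_dwells <- function(st, du, dead) {
  coalesce <- function(st, du) {
    i <- 1
    while (i < length(st)) {
      if (st[i] == st[i + 1]) {
        du[i] <- du[i] + du[i + 1]
        st <- st[-(i + 1)]; du <- du[-(i + 1)]
      } else i <- i + 1
    }
    list(st = st, du = du)
  }
  recur <- function(st, du) {
    short <- which(du < dead - 1e-12)
    if (length(short) == 0 || length(st) == 1)
      return(list(st = st, du = du))
    i <- short[1]
    if (i == 1) {
      du[2] <- du[2] + du[1]
      st <- st[-1]; du <- du[-1]
    } else {
      du[i - 1] <- du[i - 1] + du[i]
      st <- st[-i]; du <- du[-i]
    }
    z <- coalesce(st, du)
    recur(z$st, z$du)
  }
  recur(st, du)
}

# Build an idealized_trace by hand from labels (frame_interval dt).
make_idealized <- function(labels, x = NULL, dt = 0.1, zero_state = FALSE) {
  if (is.null(x)) x <- c(0, 0.52, 0.40, 0.28)[labels + 1]
  structure(list(labels = as.integer(labels), x = x,
                 state_means = c(0.52, 0.40, 0.28),
                 state_sds = rep(0.05, 3), trans = NULL, loglik = NA,
                 zero_state = zero_state, frame_interval = dt),
            class = "idealized_trace")
}

# Build a dwell_sequence by hand.
make_dwells <- function(states, durations, dead_time = 0.2, conc = NULL) {
  ds <- structure(data.frame(state = as.integer(states),
                             duration = durations,
                             start_frame = NA_integer_,
                             end_frame = NA_integer_),
                  dead_time = dead_time, frame_interval = 0.1,
                  censored_first = TRUE, censored_last = TRUE,
                  class = c("dwell_sequence", "data.frame"))
  if (!is.null(conc)) attr(ds, "conc") <- conc
  ds
}

# Reference generator settings used across tests.
ref_kp <- function(conc = 0.3) kinetic_params(kon = 1.0, koff = 0.46, conc = conc)
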