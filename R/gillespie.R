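#' Exact stochastic simulation of a state path
#'
#' Gillespie (exact continuous-time Markov) realization of a rate matrix:
#' exponential dwell in the current state at its exit rate, then a jump to a
#' neighbor with probability proportional to the outgoing rate.
#'
#' @param Q rate matrix (rows sum to zero, non-negative off-diagonals).
#' @param duration total simulated time (s).
#' @param start_state starting state: an index, a state name, or
#'   `"stationary"` to draw from the stationary distribution of `Q`.
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `state_path`: a data.frame with columns
#'   `state` (integer), `start` and `end` (s); attributes `duration` and
#'   `states` (state names).
#' @export
simulate_state_path <- function(Q, duration, start_state = "stationary",
                                seed = NULL) {
  validate_rate_matrix(Q)
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(Q)
  states <- rownames(Q)
  if (is.null(states)) states <- as.character(seq_len(n))
  if (identical(start_state, "stationary")) {
    p <- tryCatch(stationary_distribution(Q),
                  error = function(e) rep(1 / n, n))
    s <- sample.int(n, 1, prob = pmax(p, 0))
  } else if (is.character(start_state)) {
    s <- match(start_state, states)
    if (is.na(s)) stop("unknown start_state")
  } else {
    s <- as.integer(start_state)
    if (s < 1 || s > n) stop("start_state out of range")
  }

  t_cur <- 0
  cap <- 256L; len <- 0L
  st <- integer(cap); t0 <- numeric(cap); t1 <- numeric(cap)
  push <- function(state, a, b) {
    if (len == cap) {
      cap <<- cap * 2L
      length(st) <<- cap; length(t0) <<- cap; length(t1) <<- cap
    }
    len <<- len + 1L
    st[len] <<- state; t0[len] <<- a; t1[len] <<- b
  }
  repeat {
    lam <- -Q[s, s]
    if (lam <= 0) {              # absorbing: fill to the end
      push(s, t_cur, duration)
      break
    }
    dwell <- rexp(1, lam)
    t_next <- t_cur + dwell
    if (t_next >= duration) {
      push(s, t_cur, duration)
      break
    }
    push(s, t_cur, t_next)
    rates <- Q[s, ]; rates[s] <- 0
    s <- sample.int(n, 1, prob = rates / lam)
    t_cur <- t_next
  }
  idx <- seq_len(len)
  structure(data.frame(state = st[idx], start = t0[idx], end = t1[idx]),
            duration = duration, states = states, class = c("state_path", "data.frame"))
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("state_path: %d segments over %.3g s, states: %s\n",
              nrow(x), attr(x, "duration"),
              paste(attr(x, "states"), collapse = ", ")))
  NextMethod()
}
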