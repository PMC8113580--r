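# Segmental k-means (SKM) idealization: iterated Viterbi segmentation under
# Gaussian emissions with re-estimation of state means, variances and
# transition probabilities from the segmentation, until the labels fix.

# Viterbi path under Gaussian emissions. On exact score ties the path
# prefers staying in the current state, which minimizes spurious
# transitions. Returns the path and its joint log-likelihood.
viterbi_path <- function(x, means, sds, logA, logpi) {
  n <- length(x); K <- length(means)
  em <- matrix(0, n, K)
  for (k in seq_len(K)) em[, k] <- dnorm(x, means[k], sds[k], log = TRUE)
  if (n == 1) {
    s <- which.max(logpi + em[1, ])
    return(list(path = s, loglik = (logpi + em[1, ])[s]))
  }
  delta <- logpi + em[1, ]
  psi <- matrix(0L, n, K)
  for (t in 2:n) {
    new_delta <- numeric(K)
    for (k in seq_len(K)) {
      cand <- delta + logA[, k]
      m <- max(cand)
      j <- if (cand[k] >= m) k else which.max(cand)
      psi[t, k] <- j
      new_delta[k] <- cand[j] + em[t, k]
    }
    delta <- new_delta
  }
  path <- integer(n)
  path[n] <- which.max(delta)
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  list(path = path, loglik = max(delta))
}

# One SKM run over a list of numeric vectors with a shared model.
skm_engine <- function(xs, init_means, init_sds, max_iter = 100,
                       fix_transitions = FALSE, sd_floor = 0.01) {
  K <- length(init_means)
  means <- init_means; sds <- init_sds
  A <- matrix(0.05 / max(K - 1, 1), K, K); diag(A) <- if (K > 1) 0.95 else 1
  pi0 <- rep(1 / K, K)
  keep_ids <- seq_len(K)            # original state identities
  paths <- NULL; ll_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    logA <- log(A); logpi <- log(pi0)
    vit <- lapply(xs, viterbi_path, means = means, sds = sds,
                  logA = logA, logpi = logpi)
    new_paths <- lapply(vit, `[[`, "path")
    ll <- sum(vapply(vit, `[[`, 0, "loglik"))
    ll_trace <- c(ll_trace, ll)
    all_lab <- unlist(new_paths)
    counts <- tabulate(all_lab, nbins = K)
    if (any(counts == 0)) {
      drop <- which(counts == 0)
      warning(sprintf("SKM: state(s) %s received no frames; dropped",
                      paste(keep_ids[drop], collapse = ",")))
      keep <- setdiff(seq_len(K), drop)
      remap <- match(seq_len(K), keep)
      means <- means[keep]; sds <- sds[keep]
      A <- A[keep, keep, drop = FALSE]
      A <- A / rowSums(A)
      pi0 <- pi0[keep] / sum(pi0[keep])
      keep_ids <- keep_ids[keep]
      K <- length(keep)
      paths <- NULL                  # force at least one more iteration
      next
    }
    xall <- unlist(xs)
    for (k in seq_len(K)) {
      xk <- xall[all_lab == k]
      means[k] <- mean(xk)
      if (length(xk) > 1) sds[k] <- max(stats::sd(xk), sd_floor)
    }
    if (!fix_transitions) {
      C <- matrix(0, K, K)
      for (p in new_paths) {
        if (length(p) < 2) next
        from <- p[-length(p)]; to <- p[-1]
        for (i in seq_along(from)) C[from[i], to[i]] <- C[from[i], to[i]] + 1
      }
      A <- (C + 1e-9) / (rowSums(C) + K * 1e-9)
      zr <- rowSums(C) == 0
      if (any(zr)) { A[zr, ] <- 1e-9 / (1 + (K - 1) * 1e-9); diag(A)[zr] <- 1 / (1 + (K - 1) * 1e-9) }
      firsts <- vapply(new_paths, `[`, 0L, 1)
      pi0 <- (tabulate(firsts, nbins = K) + 1e-9)
      pi0 <- pi0 / sum(pi0)
    }
    if (!is.null(paths) && identical(paths, new_paths)) {
      paths <- new_paths
      break
    }
    paths <- new_paths
  }
  list(paths = paths, means = means, sds = sds, trans = A, pi0 = pi0,
       loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       state_ids = keep_ids, n_states = K)
}

# Extract a numeric FRET vector (and zero-segment flag) from supported inputs.
skm_input <- function(x) {
  if (inherits(x, "fret_trace")) {
    v <- x$fret[x$defined]
    attr(v, "frame_interval") <- x$frame_interval
    v
  } else if (is.numeric(x)) x
  else stop("inputs must be fret_trace objects or numeric vectors")
}

#' Idealize FRET traces by segmental k-means
#'
#' Iterates Viterbi segmentation under Gaussian emissions and the current
#' transition probabilities with re-estimation of state means, variances and
#' transition probabilities from the segmentation, until the labels are
#' unchanged. The best of `restarts` randomly perturbed initializations (by
#' total path likelihood) is returned. When a list of traces is given they
#' share one model (pooled re-estimation, per-trace segmentation).
#'
#' A dedicated zero-FRET class (initial mean 0) can be appended for traces
#' containing post-acceptor-bleach frames; in the output it carries label 0
#' while the conformational states are labeled 1..n in descending-mean order
#' (high / middle / low).
#'
#' @param x a `fret_trace`, numeric vector, or list of either.
#' @param n_states number of conformational states.
#' @param init_means optional initial conformational means (descending);
#'   default: quantiles of the pooled data.
#' @param include_zero append the zero-FRET class; default `NULL` uses the
#'   `has_zero` attribute of the input list (see [idealization_input()]),
#'   falling back to `FALSE`.
#' @param max_iter maximum SKM iterations.
#' @param restarts number of random initial perturbations.
#' @param fix_transitions hold transition probabilities fixed and uniform
#'   instead of re-estimating them.
#' @return For a single trace an `idealized_trace` (fields `labels`, `x`,
#'   `state_means`, `state_sds`, `trans`, `loglik`, `ll_trace`,
#'   `zero_state`, `frame_interval`); for a list an object of class
#'   `skm_fit` with shared model fields and `$traces`, a list of
#'   `idealized_trace`.
#' @export
skm_idealize <- function(x, n_states = 3, init_means = NULL,
                         include_zero = NULL, max_iter = 100, restarts = 3,
                         fix_transitions = FALSE) {
  single <- !is.list(x) || inherits(x, "fret_trace")
  xs_raw <- if (single) list(x) else x
  xs <- lapply(xs_raw, skm_input)
  frame_interval <- attr(xs[[1]], "frame_interval")
  if (is.null(frame_interval)) frame_interval <- 0.1
  if (is.null(include_zero)) {
    hz <- attr(x, "has_zero")
    include_zero <- if (is.null(hz)) FALSE else any(hz)
  }
  pooled <- unlist(xs)
  if (length(pooled) < n_states) stop("fewer frames than states")
  if (is.null(init_means)) {
    qs <- quantile(pooled[pooled > 0.15 | !include_zero],
                   probs = (2 * (n_states:1) - 1) / (2 * n_states),
                   names = FALSE, na.rm = TRUE)
    init_means <- as.numeric(qs)
  }
  if (any(duplicated(init_means))) stop("init_means must be distinct")
  K <- n_states + as.integer(include_zero)
  zero_id <- if (include_zero) K else NA_integer_
  base_means <- c(init_means, if (include_zero) 0)
  init_sds <- rep(0.06, K)

  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    m0 <- base_means
    if (r > 1) {
      m0[seq_len(n_states)] <- m0[seq_len(n_states)] +
        runif(n_states, -0.03, 0.03)
    }
    fit <- skm_engine(xs, m0, init_sds, max_iter, fix_transitions)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  fit <- best

  # relabel: conformational states descending by mean -> 1..n; zero class -> 0
  conf <- which(fit$state_ids != zero_id | is.na(zero_id))
  has_zero_state <- any(fit$state_ids == zero_id, na.rm = TRUE)
  ord <- conf[order(fit$means[conf], decreasing = TRUE)]
  new_label <- integer(fit$n_states)
  new_label[ord] <- seq_along(ord)
  if (has_zero_state) new_label[which(fit$state_ids == zero_id)] <- 0L
  remap <- function(p) new_label[p]
  state_means <- fit$means[ord]; state_sds <- fit$sds[ord]
  perm <- c(ord, if (has_zero_state) which(fit$state_ids == zero_id))
  trans <- fit$trans[perm, perm, drop = FALSE]
  lab_names <- c(seq_along(ord), if (has_zero_state) 0)
  dimnames(trans) <- list(lab_names, lab_names)

  traces <- lapply(seq_along(xs), function(i) {
    structure(list(labels = remap(fit$paths[[i]]), x = as.numeric(xs[[i]]),
                   state_means = state_means, state_sds = state_sds,
                   trans = trans, loglik = fit$loglik,
                   zero_state = has_zero_state,
                   frame_interval = frame_interval),
              class = "idealized_trace")
  })
  if (single) {
    it <- traces[[1]]
    it$ll_trace <- fit$ll_trace
    return(it)
  }
  structure(list(traces = traces, state_means = state_means,
                 state_sds = state_sds, trans = trans,
                 loglik = fit$loglik, ll_trace = fit$ll_trace,
                 zero_state = has_zero_state, n_states = length(ord),
                 frame_interval = frame_interval),
            class = "skm_fit")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf("idealized_trace: %d frames, states at %s%s\n",
              length(x$labels),
              paste(sprintf("%.3f", x$state_means), collapse = ", "),
              if (x$zero_state) " (+ zero class)" else ""))
  invisible(x)
}

#' @export
print.skm_fit <- function(x, ...) {
  cat(sprintf("skm_fit: %d traces, %d states at %s%s, loglik %.2f\n",
              length(x$traces), x$n_states,
              paste(sprintf("%.3f", x$state_means), collapse = ", "),
              if (x$zero_state) " (+ zero class)" else "", x$loglik))
  invisible(x)
}

#' Prepare selected traces for idealization
#'
#' Builds, per selected trace, the FRET vector spanning all frames up to the
#' donor bleach (including any post-acceptor-bleach zero-FRET segment) and
#' flags which traces contain such a segment, so [skm_idealize()] can decide
#' whether to include the zero-FRET class.
#'
#' @param ts a selected `trace_set` (see [select_traces()]).
#' @return A list of numeric FRET vectors with attributes `has_zero`
#'   (logical per trace) and `frame_interval`.
#' @export
idealization_input <- function(ts) {
  stopifnot(inherits(ts, "trace_set"))
  if (is.null(attr(ts, "selected"))) ts <- select_traces(ts)
  crosstalk <- if (!is.null(ts$crosstalk)) ts$crosstalk else 0.105
  gamma <- if (!is.null(ts$gamma)) ts$gamma else 1.1
  out <- list(); hz <- logical(0)
  for (tr in ts$traces) {
    ev <- tr$bleach
    n <- length(tr$donor)
    last <- if (!is.na(ev$donor_bleach_frame)) ev$donor_bleach_frame - 1L else n
    ft <- compute_fret(tr, crosstalk, gamma)
    v <- ft$fret[seq_len(last)]
    keep <- is.finite(v)
    v <- v[keep]
    attr(v, "frame_interval") <- tr$frame_interval
    out[[length(out) + 1]] <- v
    hz <- c(hz, !is.na(ev$acceptor_bleach_frame) &&
              (is.na(ev$donor_bleach_frame) ||
                 ev$acceptor_bleach_frame < ev$donor_bleach_frame))
  }
  attr(out, "has_zero") <- hz
  attr(out, "frame_interval") <- ts$frame_interval
  out
}

#' Remove the zero-FRET class from an idealized trace
#'
#' Frames labeled zero-FRET (post-acceptor-bleach) are truncated from the
#' trace end; an internal zero-FRET run (a blink) splits the trace and the
#' shorter fragment is discarded, recursively until no zero-FRET frames
#' remain.
#'
#' @param it an `idealized_trace`.
#' @return The trimmed `idealized_trace` (with `zero_state = FALSE`); an
#'   entirely zero-FRET trace yields an empty result flagged with
#'   `attr(, "empty")`.
#' @export
remove_zero_state <- function(it) {
  stopifnot(inherits(it, "idealized_trace"))
  lab <- it$labels
  if (!any(lab == 0)) return(it)
  keep_range <- function(idx) {             # idx: indices into lab
    l <- lab[idx]
    if (all(l == 0)) return(integer(0))
    idx <- idx[seq(which(l != 0)[1], max(which(l != 0)))]  # trim ends
    l <- lab[idx]
    z <- which(l == 0)
    if (length(z) == 0) return(idx)
    # first internal zero run
    r0 <- z[1]
    r1 <- r0
    while (r1 < length(l) && l[r1 + 1] == 0) r1 <- r1 + 1
    left <- idx[seq_len(r0 - 1)]
    right <- idx[(r1 + 1):length(idx)]
    if (length(left) >= length(right)) keep_range(left) else keep_range(right)
  }
  idx <- keep_range(seq_along(lab))
  out <- it
  out$labels <- lab[idx]
  out$x <- it$x[idx]
  out$zero_state <- FALSE
  if (length(idx) == 0) attr(out, "empty") <- TRUE
  out
}
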