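# Dwell-time maximum-likelihood (MIL-style) fitting of the three-state
# binding scheme. Because each FRET class contains exactly one kinetic
# state, the aggregated-state interval likelihood reduces exactly to
# truncated-exponential dwell densities with branching probabilities; the
# dead time enters by conditioning each dwell density on t >= dead_time
# (first-order missed-event treatment).

#' Specify a kinetic scheme for dwell-time fitting
#'
#' The linear topology is R <-> RA <-> RAA (states 1, 2, 3 mapping to the
#' high, middle and low FRET classes); the triangular topology adds a direct
#' R <-> RAA edge and is only available with free rates. The
#' `"independent_sites"` constraint has two parameters (kon, koff) with
#' R->RA = `2 kon conc`, RA->RAA = `kon conc`, RAA->RA = `2 koff`,
#' RA->R = `koff`; `"free"` fits one rate per edge direction.
#'
#' @param topology `"linear"` or `"triangular"`.
#' @param constraint `"independent_sites"` or `"free"`.
#' @param conc ligand concentration (uM); needed by the constrained scheme.
#' @return An object of class `scheme_spec`.
#' @export
scheme_spec <- function(topology = c("linear", "triangular"),
                        constraint = c("independent_sites", "free"),
                        conc = NA_real_) {
  topology <- match.arg(topology)
  constraint <- match.arg(constraint)
  if (topology == "triangular" && constraint != "free")
    stop("triangular topology requires free rates")
  structure(list(topology = topology, constraint = constraint, conc = conc),
            class = "scheme_spec")
}

scheme_par_names <- function(scheme) {
  if (scheme$constraint == "independent_sites") return(c("kon", "koff"))
  base <- c("r12", "r21", "r23", "r32")
  if (scheme$topology == "triangular") c(base, "r13", "r31") else base
}

# 3x3 generator from a named rate vector under the scheme (conc in uM).
scheme_rate_matrix <- function(scheme, rates, conc = NULL) {
  if (is.null(conc)) conc <- scheme$conc
  Q <- matrix(0, 3, 3, dimnames = list(c("R", "RA", "RAA"),
                                       c("R", "RA", "RAA")))
  if (scheme$constraint == "independent_sites") {
    if (!is.finite(conc) || conc <= 0)
      stop("constrained scheme needs a known positive concentration")
    kp <- kinetic_params(rates[["kon"]], rates[["koff"]], conc)
    return(build_rate_matrix(kp))
  }
  Q[1, 2] <- rates[["r12"]]; Q[2, 1] <- rates[["r21"]]
  Q[2, 3] <- rates[["r23"]]; Q[3, 2] <- rates[["r32"]]
  if (scheme$topology == "triangular") {
    Q[1, 3] <- rates[["r13"]]; Q[3, 1] <- rates[["r31"]]
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Apparent exit rates and branching probabilities under the dead time.
# Merging sweeps any dwell shorter than the dead time into its neighbors, so
# (a) an observed i -> j transition may really be i -> k -> j with an
# unresolved dwell in k; to first order the apparent i -> j rate is
#   q_app_ij = q_ij + sum_k q_ik (1 - exp(-lambda_k td)) q_kj / lambda_k ,
# and (b) an invisible excursion i -> k -> i extends the apparent dwell in
# i, lowering its apparent exit rate to
#   lambda_app_i = lambda_i - sum_k q_ik (1 - exp(-lambda_k td)) q_ki / lambda_k .
# Branch probabilities are renormalized so the per-dwell density integrates
# to one. `mode = "conditional"` keeps the uncorrected exit rates (pure
# conditioning on t >= dead time); both reduce to q_ij / lambda_i at zero
# dead time.
effective_branching <- function(Q, dead_time,
                                mode = c("first_order", "conditional")) {
  mode <- match.arg(mode)
  lam <- -diag(Q)
  K <- nrow(Q)
  Qe <- Q; diag(Qe) <- 0
  lam_app <- lam
  if (dead_time > 0) {
    miss <- ifelse(lam > 0, (1 - exp(-lam * dead_time)) / lam, 0)
    for (i in seq_len(K)) {
      for (j in seq_len(K)) {
        if (i == j) next
        ks <- setdiff(seq_len(K), c(i, j))
        Qe[i, j] <- Q[i, j] + sum(Q[i, ks] * miss[ks] * Q[ks, j])
      }
      if (mode == "first_order") {
        ks <- setdiff(seq_len(K), i)
        lam_app[i] <- max(lam[i] - sum(Q[i, ks] * miss[ks] * Q[ks, i]),
                          1e-12)
      }
    }
  }
  B <- Qe / pmax(rowSums(Qe), 1e-300)
  list(lam = lam_app, B = B)
}

as_dwell_list <- function(ds) {
  if (inherits(ds, "dwell_sequence")) list(ds)
  else {
    stopifnot(all(vapply(ds, inherits, TRUE, "dwell_sequence")))
    ds
  }
}

#' Log-likelihood of dwell sequences under a kinetic scheme
#'
#' Each non-final dwell in state i of duration t, ending in state j,
#' contributes `log(lambda_i B_ij) - lambda_i (t - dead_time)` where
#' `lambda_i` is the exit rate of state i and `B_ij` the branching
#' probability of the observed i -> j transition (the dead-time-conditioned
#' exponential density times the branch). Because dead-time merging can make
#' a transition appear to skip the intermediate state, the branch matrix
#' uses first-order effective rates
#' `q_ij + sum_k q_ik (1 - exp(-lambda_k dead_time)) q_kj / lambda_k`,
#' renormalized per state; at zero dead time this is exactly
#' `q_ij / lambda_i`. The censored final dwell contributes only the survivor term
#' `-lambda_i (t - dead_time)`; set `include_censored = FALSE` to drop first
#' and last dwells instead. Sequences from different concentrations can be
#' mixed for a constrained scheme by attaching a `conc` attribute to each
#' `dwell_sequence`.
#'
#' @param ds a `dwell_sequence` or list of them.
#' @param scheme a [scheme_spec()].
#' @param rates named rate vector (see [scheme_spec()] for names).
#' @param dead_time dead time (s); defaults to the sequences' own.
#' @param include_censored include first/last dwells (default TRUE).
#' @param missed_events `"first_order"` (default) also corrects the
#'   apparent exit rates for invisible sub-dead-time excursions that return
#'   to the same state; `"conditional"` keeps the plain exit rates and only
#'   conditions each dwell on t >= dead_time.
#' @return The summed log-likelihood (a single number).
#' @export
dwell_loglik <- function(ds, scheme, rates, dead_time = NULL,
                         include_censored = TRUE,
                         missed_events = c("first_order", "conditional")) {
  missed_events <- match.arg(missed_events)
  ds <- as_dwell_list(ds)
  if (any(!is.finite(unlist(rates))) || any(unlist(rates) <= 0))
    stop("rates must be positive and finite")
  ll <- 0
  for (s in ds) {
    if (nrow(s) == 0) next
    td <- if (is.null(dead_time)) attr(s, "dead_time") else dead_time
    if (is.null(td)) td <- 0
    if (any(s$duration < td - 1e-9))
      stop("dwell shorter than the dead time; extract dwells with merging")
    conc <- attr(s, "conc")
    Q <- scheme_rate_matrix(scheme, rates, conc)
    eb <- effective_branching(Q, td, missed_events)
    lam <- eb$lam
    n <- nrow(s)
    rows <- if (include_censored) seq_len(n) else
      if (n > 2) 2:(n - 1) else integer(0)
    if (length(rows) == 0) next
    st <- s$state[rows]
    ll <- ll - sum(lam[st] * (s$duration[rows] - td))
    tr <- rows[rows < n]                 # dwells whose exit is observed
    if (length(tr) > 0) {
      p <- lam[s$state[tr]] * eb$B[cbind(s$state[tr], s$state[tr + 1])]
      if (any(p <= 0)) return(-Inf)
      ll <- ll + sum(log(p))
    }
  }
  ll
}

#' Maximum-likelihood fit of scheme rates to dwell sequences
#'
#' Maximizes [dwell_loglik()] in log-rate space with multiple starts
#' (perturbations of +/- half a decade around a moment-based initial point),
#' bounded to keep rates in a wide positive range. Standard errors come from
#' the inverse observed information (numerical Hessian at the optimum); a
#' rate pinned at the search boundary is flagged as a very low (or high)
#' probability transition and its SE reported as NA. For the constrained
#' scheme the fit reports kon, koff and Kd = koff/kon with a delta-method
#' SE.
#'
#' @param ds a `dwell_sequence` or list of them.
#' @param scheme a [scheme_spec()].
#' @param init optional named initial rate vector.
#' @param n_starts number of optimization starts.
#' @param dead_time dead time (s); defaults to the sequences' own.
#' @param include_censored include first/last dwells via survivor terms.
#' @param missed_events missed-event treatment, see [dwell_loglik()].
#' @param lower,upper rate search bounds.
#' @return An object of class `mil_fit`: `rates`, `se`, `loglik`,
#'   `n_dwells`, `kd` and `kd_se` (constrained fits), `pinned` (logical per
#'   rate), `converged`, `scheme`, `vcov_log`.
#' @export
fit_rates <- function(ds, scheme, init = NULL, n_starts = 5,
                      dead_time = NULL, include_censored = TRUE,
                      missed_events = c("first_order", "conditional"),
                      lower = 1e-6, upper = 1e4) {
  missed_events <- match.arg(missed_events)
  ds <- as_dwell_list(ds)
  pn <- scheme_par_names(scheme)
  n_dwells <- sum(vapply(ds, nrow, 0L))
  if (n_dwells < 50)
    warning("fewer than 50 dwells; rate estimates will be unstable")
  if (is.null(init)) init <- moment_init(ds, scheme, dead_time)
  init <- pmin(pmax(init[pn], lower * 10), upper / 10)

  # flatten sequences once, grouped by concentration, for fast evaluation
  comp <- compile_dwells(ds, scheme, dead_time, include_censored)
  nll <- function(logp) {
    r <- setNames(exp(logp), pn)
    ll <- 0
    for (g in comp) {
      Q <- scheme_rate_matrix(scheme, r, g$conc)
      eb <- effective_branching(Q, g$dead_time, missed_events)
      ll <- ll - sum(eb$lam[g$st] * g$excess)
      p <- eb$lam[g$from] * eb$B[cbind(g$from, g$to)]
      if (any(p <= 0)) return(Inf)
      ll <- ll + sum(log(p))
    }
    -ll
  }
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    lp0 <- log(init)
    if (s > 1) lp0 <- lp0 + log(10) * runif(length(pn), -0.5, 0.5)
    lp0 <- pmin(pmax(lp0, log(lower)), log(upper))
    fit <- tryCatch(
      optim(lp0, nll, method = "L-BFGS-B",
            lower = log(lower), upper = log(upper),
            control = list(maxit = 1000, factr = 1e2)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("all optimization starts failed")
  lp <- best$par
  rates <- setNames(exp(lp), pn)
  pinned <- lp <= log(lower) + 1e-3 | lp >= log(upper) - 1e-3
  se <- rep(NA_real_, length(pn)); names(se) <- pn
  vcov_log <- matrix(NA_real_, length(pn), length(pn),
                     dimnames = list(pn, pn))
  if (!any(pinned)) {
    H <- tryCatch(optimHess(lp, nll), error = function(e) NULL)
    if (!is.null(H)) {
      V <- tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(V) && all(is.finite(diag(V))) && all(diag(V) >= 0)) {
        vcov_log <- V
        se <- rates * sqrt(diag(V))    # delta method from log space
      }
    }
  }
  kd <- kd_se <- NA_real_
  if (scheme$constraint == "independent_sites") {
    kd <- unname(rates["koff"] / rates["kon"])
    if (all(is.finite(vcov_log[c("kon", "koff"), c("kon", "koff")]))) {
      v <- vcov_log["koff", "koff"] + vcov_log["kon", "kon"] -
        2 * vcov_log["koff", "kon"]
      kd_se <- kd * sqrt(max(v, 0))
    }
  }
  structure(list(rates = rates, se = se, loglik = -best$value,
                 n_dwells = n_dwells, kd = kd, kd_se = kd_se,
                 pinned = setNames(pinned, pn),
                 converged = best$convergence == 0 && !any(pinned),
                 message = best$message, scheme = scheme,
                 vcov_log = vcov_log),
            class = "mil_fit")
}

# Flatten dwell sequences into per-concentration groups of vectors:
# st/excess for duration terms, from/to for observed transitions.
compile_dwells <- function(ds, scheme, dead_time, include_censored) {
  key <- vapply(ds, function(s) {
    cc <- attr(s, "conc"); if (is.null(cc)) NA_real_ else cc
  }, 0)
  td_seq <- vapply(ds, function(s) {
    if (is.null(dead_time)) {
      a <- attr(s, "dead_time"); if (is.null(a)) 0 else a
    } else dead_time
  }, 0)
  key2 <- ifelse(is.na(key), -Inf, key)   # NA conc = use the scheme's
  groups <- split(seq_along(ds),
                  paste(format(key2, digits = 15), format(td_seq, digits = 15)))
  lapply(groups, function(idx) {
    st <- integer(0); excess <- numeric(0)
    from <- integer(0); to <- integer(0)
    td <- td_seq[idx[1]]
    for (i in idx) {
      s <- ds[[i]]
      n <- nrow(s)
      if (n == 0) next
      if (any(s$duration < td - 1e-9))
        stop("dwell shorter than the dead time; extract dwells with merging")
      rows <- if (include_censored) seq_len(n) else
        if (n > 2) 2:(n - 1) else integer(0)
      if (length(rows) == 0) next
      st <- c(st, s$state[rows])
      excess <- c(excess, s$duration[rows] - td)
      tr <- rows[rows < n]
      from <- c(from, s$state[tr]); to <- c(to, s$state[tr + 1])
    }
    cc <- key[idx[1]]
    list(st = st, excess = excess, from = from, to = to,
         conc = if (is.na(cc)) NULL else cc, dead_time = td)
  })
}

# Moment-based initial rates: counts of i->j transitions over the
# dead-time-corrected time spent in i.
moment_init <- function(ds, scheme, dead_time = NULL) {
  C <- matrix(0, 3, 3); Tm <- rep(1e-9, 3)
  conc <- scheme$conc
  for (s in ds) {
    td <- if (is.null(dead_time)) attr(s, "dead_time") else dead_time
    if (is.null(td)) td <- 0
    n <- nrow(s)
    if (n == 0) next
    if (!is.null(attr(s, "conc"))) conc <- attr(s, "conc")
    for (i in seq_len(n)) {
      st <- s$state[i]
      Tm[st] <- Tm[st] + max(s$duration[i] - td, 1e-6)
      if (i < n) C[st, s$state[i + 1]] <- C[st, s$state[i + 1]] + 1
    }
  }
  qh <- pmax(C / Tm, 1e-3)          # rows: from-state
  if (scheme$constraint == "independent_sites") {
    if (!is.finite(conc) || conc <= 0) conc <- 1
    c(kon = unname((qh[1, 2] / 2 + qh[2, 3]) / (2 * conc)),
      koff = unname((qh[2, 1] + qh[3, 2] / 2) / 2))
  } else {
    out <- c(r12 = qh[1, 2], r21 = qh[2, 1], r23 = qh[2, 3], r32 = qh[3, 2])
    if (scheme$topology == "triangular")
      out <- c(out, r13 = qh[1, 3], r31 = qh[3, 1])
    out
  }
}

#' @export
print.mil_fit <- function(x, ...) {
  cat(sprintf("mil_fit (%s, %s): loglik = %.2f over %d dwells%s\n",
              x$scheme$topology, x$scheme$constraint, x$loglik, x$n_dwells,
              if (x$converged) "" else " [not converged]"))
  tab <- data.frame(rate = names(x$rates), value = unname(x$rates),
                    se = unname(x$se), pinned = unname(x$pinned))
  print(tab, digits = 4, row.names = FALSE)
  if (is.finite(x$kd))
    cat(sprintf("Kd = koff/kon = %.4g uM (SE %.2g)\n", x$kd, x$kd_se))
  invisible(x)
}

#' Dissociation constant from a constrained fit
#'
#' `Kd = koff / kon` (uM) with its delta-method standard error. Only defined
#' for the independent-sites constrained scheme.
#'
#' @param fit a `mil_fit`.
#' @return Named list with `kd` and `se`.
#' @export
dissociation_constant <- function(fit) {
  stopifnot(inherits(fit, "mil_fit"))
  if (fit$scheme$constraint != "independent_sites")
    stop("Kd is undefined without the independent-sites constraint")
  list(kd = fit$kd, se = fit$kd_se)
}

#' Fit and compare alternative kinetic schemes
#'
#' Fits each scheme independently and tabulates log-likelihoods, parameter
#' counts, convergence and boundary-pinned rates (the signature of a
#' very-low-probability transition). Per-scheme failures are reported in the
#' table, never aborted on.
#'
#' @param ds a `dwell_sequence` or list of them.
#' @param schemes named list of [scheme_spec()] objects.
#' @param ... passed to [fit_rates()].
#' @return A data.frame with one row per scheme (`scheme`, `topology`,
#'   `constraint`, `n_par`, `loglik`, `dloglik` relative to the best linear
#'   free fit when present else the maximum, `converged`, `pinned_rates`);
#'   attribute `fits` holds the underlying `mil_fit` objects.
#' @export
compare_schemes <- function(ds, schemes, ...) {
  stopifnot(length(schemes) >= 2)
  if (is.null(names(schemes)))
    names(schemes) <- paste0("scheme", seq_along(schemes))
  fits <- lapply(schemes, function(sc) {
    tryCatch(fit_rates(ds, sc, ...), error = function(e) e)
  })
  rows <- lapply(names(schemes), function(nm) {
    f <- fits[[nm]]; sc <- schemes[[nm]]
    if (inherits(f, "error")) {
      data.frame(scheme = nm, topology = sc$topology,
                 constraint = sc$constraint,
                 n_par = length(scheme_par_names(sc)),
                 loglik = NA_real_, converged = FALSE,
                 pinned_rates = paste("error:", conditionMessage(f)))
    } else {
      data.frame(scheme = nm, topology = sc$topology,
                 constraint = sc$constraint, n_par = length(f$rates),
                 loglik = f$loglik, converged = f$converged,
                 pinned_rates = paste(names(f$rates)[f$pinned],
                                      collapse = ","))
    }
  })
  tab <- do.call(rbind, rows)
  ref_idx <- which(tab$topology == "linear" & tab$constraint == "free" &
                     is.finite(tab$loglik))
  ref <- if (length(ref_idx) > 0) tab$loglik[ref_idx[1]] else
    suppressWarnings(max(tab$loglik, na.rm = TRUE))
  tab$dloglik <- tab$loglik - ref
  attr(tab, "fits") <- fits
  tab
}
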