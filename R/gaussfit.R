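# Gaussian curve fits to binned FRET density: a curve fit to the histogram
# (mirroring interactive peak-fitting practice), not sample-based mixture
# estimation. Components are always reported in descending-mean order
# (high / middle / low FRET).

gauss_mix <- function(x, means, sds, areas) {
  y <- 0
  for (j in seq_along(means)) y <- y + areas[j] * dnorm(x, means[j], sds[j])
  y
}

# quantile-based initial means from the binned density
density_quantiles <- function(h, p) {
  w <- h$density / sum(h$density)
  cw <- cumsum(w)
  vapply(p, function(q) h$mids[which(cw >= q)[1]], 0)
}

default_gauss_bounds <- function(k) {
  list(lower = c(rep(0, k), rep(0.01, k), rep(0, k)),
       upper = c(rep(1, k), rep(0.2, k), rep(1.5, k)))
}

fit_gauss_curve <- function(x, y, w, init, lower, upper, k) {
  resid_fn <- function(p) {
    sqrt(w) * (y - gauss_mix(x, p[1:k], p[k + 1:k], p[2 * k + 1:k]))
  }
  fit <- minpack.lm::nls.lm(par = init, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-12, ptol = 1e-12))
  list(par = fit$par, ssr = sum(fit$fvec^2), info = fit$info,
       message = fit$message)
}

#' Fit a sum of Gaussian components to a FRET histogram
#'
#' Weighted least-squares fit of `k` Gaussians to the binned density
#' evaluated at bin midpoints, with multiple starts from quantile-based
#' initial means. Components are ordered by descending mean and carry the
#' FWHM (`2 sqrt(2 ln 2) sd`).
#'
#' @param h a `fret_histogram`.
#' @param k number of components (1 to 3 typical).
#' @param init optional initial parameter vector
#'   `c(means, sds, areas)` of length `3 k`.
#' @param bounds optional list with `lower` and `upper` vectors of length
#'   `3 k`; defaults keep means in \[0, 1\] and sds in \[0.01, 0.2\] to
#'   prevent component collapse.
#' @param weights `"equal"` (default) or `"poisson"` (weight 1/max(y, eps)).
#' @param n_starts random restarts around the initial point.
#' @return An object of class `gauss_fit`: data.frame `components`
#'   (mean, sd, area, fwhm, ordered descending by mean), `ssr`, `converged`,
#'   `k`.
#' @export
fit_gaussians <- function(h, k = 3, init = NULL, bounds = NULL,
                          weights = c("equal", "poisson"), n_starts = 5) {
  stopifnot(inherits(h, "fret_histogram"), k >= 1)
  weights <- match.arg(weights)
  x <- h$mids; y <- h$density
  if (k > sum(y > 0)) stop("more components than occupied bins")
  w <- if (weights == "equal") rep(1, length(y)) else 1 / pmax(y, 1e-3)
  if (is.null(bounds)) bounds <- default_gauss_bounds(k)
  if (is.null(init)) {
    m0 <- density_quantiles(h, (2 * seq_len(k) - 1) / (2 * k))
    init <- c(m0, rep(0.05, k), rep(1 / k, k))
  }
  best <- fit_gauss_curve(x, y, w, init, bounds$lower, bounds$upper, k)
  if (n_starts > 1) {
    for (s in seq_len(n_starts - 1)) {
      jit <- init
      jit[1:k] <- pmin(pmax(init[1:k] + runif(k, -0.05, 0.05),
                            bounds$lower[1:k]), bounds$upper[1:k])
      cand <- tryCatch(
        fit_gauss_curve(x, y, w, jit, bounds$lower, bounds$upper, k),
        error = function(e) NULL)
      if (!is.null(cand) && cand$ssr < best$ssr) best <- cand
    }
  }
  if (!best$info %in% 1:4)
    warning("Gaussian fit did not converge cleanly: ", best$message)
  p <- best$par
  ord <- order(p[1:k], decreasing = TRUE)
  comp <- data.frame(mean = p[1:k][ord], sd = p[k + 1:k][ord],
                     area = p[2 * k + 1:k][ord])
  comp$fwhm <- 2 * sqrt(2 * log(2)) * comp$sd
  structure(list(components = comp, ssr = best$ssr,
                 converged = best$info %in% 1:4, k = k),
            class = "gauss_fit")
}

#' @export
print.gauss_fit <- function(x, ...) {
  cat(sprintf("gauss_fit: %d component(s), ssr = %.4g%s\n", x$k, x$ssr,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components, digits = 4)
  invisible(x)
}

#' Global multi-component Gaussian fit across a histogram series
#'
#' Means (and by default sds) are shared across all histograms; component
#' areas are free per histogram. This is the standard global fit for a
#' concentration series where the states themselves do not move, only their
#' occupancies.
#'
#' @param histograms list of >= 3 `fret_histogram` on identical bins.
#' @param k number of shared components.
#' @param share_sd share sds across histograms (default TRUE).
#' @param init optional vector `c(means, sds)` of shared initial values.
#' @param n_starts random restarts.
#' @return An object of class `global_gauss_fit`: `components` (shared
#'   mean/sd in descending-mean order, with fwhm), `areas` (matrix,
#'   histograms x components, same order), `conc` (per-histogram
#'   concentration if present in the histogram conditions), `ssr`,
#'   `n_par`.
#' @export
global_fit <- function(histograms, k = 3, share_sd = TRUE, init = NULL,
                       n_starts = 5) {
  stopifnot(length(histograms) >= 3,
            all(vapply(histograms, inherits, TRUE, "fret_histogram")))
  nh <- length(histograms)
  x <- histograms[[1]]$mids
  for (h in histograms)
    if (!isTRUE(all.equal(h$mids, x))) stop("histograms have differing bins")
  Y <- do.call(rbind, lapply(histograms, `[[`, "density"))

  pooled <- new_fret_histogram(histograms[[1]]$breaks, colMeans(Y),
                               n_molecules = 0)
  if (is.null(init)) {
    m0 <- density_quantiles(pooled, (2 * seq_len(k) - 1) / (2 * k))
    init_shared <- c(m0, rep(0.05, if (share_sd) k else 0))
  } else init_shared <- init
  n_sd <- if (share_sd) k else k * nh
  # parameter layout: k means | n_sd sds | k areas per histogram
  unpack <- function(p) {
    means <- p[1:k]
    sds <- if (share_sd) p[k + 1:k] else NULL
    areas <- matrix(p[(k + n_sd + 1):length(p)], nrow = nh, byrow = TRUE)
    list(means = means, sds = sds, areas = areas, p = p)
  }
  resid_fn <- function(p) {
    u <- unpack(p)
    unlist(lapply(seq_len(nh), function(i) {
      sds <- if (share_sd) u$sds else p[k + (i - 1) * k + 1:k]
      Y[i, ] - gauss_mix(x, u$means, sds, u$areas[i, ])
    }))
  }
  lower <- c(rep(0, k), rep(0.01, n_sd), rep(0, k * nh))
  upper <- c(rep(1, k), rep(0.2, n_sd), rep(1.5, k * nh))
  p0 <- c(init_shared[1:k],
          if (share_sd) init_shared[k + 1:k] else rep(0.05, n_sd),
          rep(1 / k, k * nh))
  run <- function(p) {
    fit <- minpack.lm::nls.lm(par = p, lower = lower, upper = upper,
                              fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 1000, ftol = 1e-12, ptol = 1e-12))
    list(par = fit$par, ssr = sum(fit$fvec^2), info = fit$info)
  }
  best <- run(p0)
  for (s in seq_len(max(0, n_starts - 1))) {
    p_j <- p0
    p_j[1:k] <- pmin(pmax(p0[1:k] + runif(k, -0.05, 0.05), 0), 1)
    cand <- tryCatch(run(p_j), error = function(e) NULL)
    if (!is.null(cand) && cand$ssr < best$ssr) best <- cand
  }
  u <- unpack(best$par)
  ord <- order(u$means, decreasing = TRUE)
  comp <- data.frame(mean = u$means[ord],
                     sd = if (share_sd) u$sds[ord] else NA_real_)
  comp$fwhm <- 2 * sqrt(2 * log(2)) * comp$sd
  areas <- u$areas[, ord, drop = FALSE]
  if (k <= 3) colnames(areas) <- c("high", "middle", "low")[seq_len(k)]
  conc <- vapply(histograms, function(h) {
    cc <- h$condition$conc
    if (is.null(cc)) NA_real_ else as.numeric(cc)
  }, 0)
  structure(list(components = comp, areas = areas, conc = conc,
                 ssr = best$ssr, converged = best$info %in% 1:4,
                 n_par = length(best$par), k = k, share_sd = share_sd),
            class = "global_gauss_fit")
}

#' @export
print.global_gauss_fit <- function(x, ...) {
  cat(sprintf("global_gauss_fit: %d components over %d histograms, ssr = %.4g\n",
              x$k, nrow(x$areas), x$ssr))
  print(x$components, digits = 4)
  invisible(x)
}
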