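#' Fit a three-parameter logistic (Hill) dose-response curve
#'
#' Fits `f(c) = fmax / (1 + (ec50 / c)^h)` to activated-state occupancies
#' (typically the low-FRET Gaussian areas) over a concentration series.
#' Zero-concentration points cannot sit on a log axis and are excluded from
#' the fitted abscissa; the three-parameter logistic already forces
#' `f(0) = 0`, which is exactly the baseline they would constrain.
#'
#' @param conc concentrations (uM).
#' @param occupancy occupancies in \[0, 1\], same length as `conc`.
#' @return An object of class `dose_response_fit` with `ec50`, `hill`,
#'   `fmax`, their standard errors, `ssr` and the data used.
#' @examples
#' cc <- 10^seq(-2, 2, length.out = 8)
#' occ <- 1 / (1 + (0.6 / cc)^1.35)
#' fit_dose_response(cc, occ)
#' @export
fit_dose_response <- function(conc, occupancy) {
  stopifnot(is.numeric(conc), is.numeric(occupancy),
            length(conc) == length(occupancy))
  pos <- conc > 0
  cc <- conc[pos]; occ <- occupancy[pos]
  if (length(unique(cc)) < 4)
    stop("need at least 4 positive concentrations")
  rng <- range(occ)
  if (rng[2] - rng[1] < 0.1 * max(rng[2], 1e-12) || rng[2] < 1e-6)
    stop("occupancies do not span the transition; fit unidentifiable")

  half <- rng[1] + (rng[2] - rng[1]) / 2
  o <- order(cc)
  ec0 <- tryCatch(approx(occ[o], cc[o], xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(ec0)) ec0 <- exp(mean(log(cc)))
  p0 <- c(fmax = max(occ), ec50 = ec0, h = 1)
  resid_fn <- function(p) occ - p[1] / (1 + (p[2] / cc)^p[3])
  fit <- minpack.lm::nls.lm(par = p0, lower = c(1e-6, 1e-9, 0.05),
                            upper = c(1.5, 1e9, 20), fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-14))
  p <- fit$par
  ssr <- sum(fit$fvec^2)
  dof <- length(cc) - 3
  se <- rep(NA_real_, 3)
  if (dof > 0) {
    vc <- tryCatch({
      s2 <- ssr / dof
      f <- function(p) p[1] / (1 + (p[2] / cc)^p[3])
      J <- vapply(1:3, function(j) {
        hj <- max(1e-6, 1e-6 * abs(p[j]))
        pp <- p; pp[j] <- pp[j] + hj
        pm <- p; pm[j] <- pm[j] - hj
        (f(pp) - f(pm)) / (2 * hj)
      }, numeric(length(cc)))
      s2 * solve(crossprod(J))
    }, error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }
  structure(list(fmax = unname(p[1]), ec50 = unname(p[2]), hill = unname(p[3]),
                 se = setNames(se, c("fmax", "ec50", "hill")),
                 ssr = ssr, converged = fit$info %in% 1:4,
                 data = data.frame(conc = cc, occupancy = occ)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("dose_response_fit: EC50 = %.4g uM (SE %.2g), h = %.3g (SE %.2g), fmax = %.3g (SE %.2g)\n",
              x$ec50, x$se["ec50"], x$hill, x$se["hill"], x$fmax,
              x$se["fmax"]))
  invisible(x)
}

#' Two-tailed Student t comparison of two groups
#'
#' Pooled-variance Student t for unpaired data, paired t on differences when
#' `paired = TRUE`. When both groups have zero variance and equal means the
#' comparison is reported as P = 1 by convention (t = 0).
#'
#' @param a,b numeric vectors (equal length when paired).
#' @param paired paired comparison flag.
#' @return List with `statistic`, `p.value`, `df`, `method`.
#' @export
compare_groups <- function(a, b, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2, length(b) >= 2)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal group sizes")
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    same <- if (paired) all(a == b) else mean(a) == mean(b)
    return(list(statistic = if (same) 0 else Inf,
                p.value = if (same) 1 else 0,
                df = if (paired) length(a) - 1 else length(a) + length(b) - 2,
                method = if (paired) "paired t" else "pooled-variance t"))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                      alternative = "two.sided")
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter),
       method = if (paired) "paired t" else "pooled-variance t")
}
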