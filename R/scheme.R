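#' Build the rate matrix of the linear two-site binding scheme
#'
#' Constructs the 3x3 generator matrix over states R (resting), RA (one site
#' occupied) and RAA (both sites occupied) for two identical, independent
#' binding sites: R -> RA at `2 kon conc`, RA -> RAA at `kon conc`,
#' RAA -> RA at `2 koff` and RA -> R at `koff`. Direct R <-> RAA entries are
#' zero and every row sums to zero.
#'
#' @param kp a [kinetic_params()] object.
#' @return A 3x3 rate matrix with dimnames `c("R","RA","RAA")`.
#' @export
build_rate_matrix <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  states <- c("R", "RA", "RAA")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  Q["R", "RA"]   <- 2 * kp$kon * kp$conc
  Q["RA", "RAA"] <- kp$kon * kp$conc
  Q["RA", "R"]   <- kp$koff
  Q["RAA", "RA"] <- 2 * kp$koff
  diag(Q) <- -rowSums(Q)
  Q
}

validate_rate_matrix <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != ncol(Q))
    stop("Q must be a square matrix")
  if (any(!is.finite(Q))) stop("Q must be finite")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(diag(Q) > 1e-12)) stop("diagonal of a rate matrix must be <= 0")
  if (any(abs(rowSums(Q)) > 1e-8 * (1 + max(abs(Q)))))
    stop("rows of a rate matrix must sum to zero")
  invisible(Q)
}

#' Stationary distribution of a rate matrix
#'
#' Solves `pi %*% Q = 0` with `sum(pi) = 1` by replacing one balance equation
#' with the normalization constraint.
#'
#' @param Q a valid rate matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(Q) {
  validate_rate_matrix(Q)
  n <- nrow(Q)
  A <- t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1), 1)
  p <- solve(A, b)
  p[p < 0 & p > -1e-12] <- 0
  names(p) <- rownames(Q)
  p
}

#' Equilibrium state occupancy of the independent two-site scheme
#'
#' With per-site occupancy `theta = conc / (conc + Kd)` and `Kd = koff/kon`,
#' the equilibrium occupancies are binomial:
#' `(p_R, p_RA, p_RAA) = ((1-theta)^2, 2 theta (1-theta), theta^2)`.
#'
#' @param kp a [kinetic_params()] object.
#' @return Named probability vector over R, RA, RAA.
#' @export
equilibrium_occupancy <- function(kp) {
  stopifnot(inherits(kp, "kinetic_params"))
  kd <- kp$koff / kp$kon
  theta <- kp$conc / (kp$conc + kd)
  c(R = (1 - theta)^2, RA = 2 * theta * (1 - theta), RAA = theta^2)
}

#' Predicted dose-response of the doubly bound (activated) state
#'
#' Evaluates the equilibrium RAA occupancy `theta^2` over a concentration
#' grid. The half-maximal concentration of this curve is analytically
#' `Kd / (sqrt(2) - 1)`, about `2.41 Kd`.
#'
#' @param kp a [kinetic_params()] object (its `conc` field is ignored).
#' @param conc numeric vector of concentrations (uM), all `>= 0`.
#' @return A data.frame with columns `conc` and `occupancy`.
#' @export
predicted_dose_response <- function(kp, conc) {
  stopifnot(inherits(kp, "kinetic_params"), is.numeric(conc))
  if (any(conc < 0)) stop("conc must be >= 0")
  kd <- kp$koff / kp$kon
  theta <- conc / (conc + kd)
  data.frame(conc = conc, occupancy = theta^2)
}
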