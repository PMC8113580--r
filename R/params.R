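#' Kinetic parameters of the two-site binding scheme
#'
#' Container for the per-site association and dissociation rate constants and
#' the ligand (glutamate) concentration. The receptor carries two identical,
#' independent ligand-binding sites, so the resting state R binds at rate
#' `2 * kon * conc`, the singly occupied state RA binds the second ligand at
#' `kon * conc`, and dissociation runs at `koff` (RA -> R) and `2 * koff`
#' (RAA -> RA).
#'
#' @param kon association rate constant per site (1/uM/s).
#' @param koff dissociation rate constant per site (1/s).
#' @param conc ligand concentration (uM).
#' @return An object of class `kinetic_params`.
#' @examples
#' kp <- kinetic_params(kon = 1, koff = 0.46, conc = 0.3)
#' build_rate_matrix(kp)
#' @export
kinetic_params <- function(kon = 1.0, koff = 0.46, conc = 0.3) {
  stopifnot(is.numeric(kon), is.numeric(koff), is.numeric(conc))
  if (!is.finite(kon) || !is.finite(koff) || !is.finite(conc))
    stop("kinetic parameters must be finite")
  if (kon <= 0) stop("kon must be > 0")
  if (koff <= 0) stop("koff must be > 0")
  if (conc < 0) stop("conc must be >= 0")
  structure(list(kon = kon, koff = koff, conc = conc),
            class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("kinetic_params: kon = %.4g 1/uM/s, koff = %.4g 1/s, conc = %.4g uM (Kd = %.4g uM)\n",
              x$kon, x$koff, x$conc, x$koff / x$kon))
  invisible(x)
}

#' Emission and detection parameters for trace rendering
#'
#' FRET means per conformational state (high to low, i.e. R, RA, RAA),
#' mean corrected total intensity, per-channel Gaussian noise, donor-to-
#' acceptor crosstalk and the gamma detection-efficiency ratio. The default
#' `noise_sd` is chosen so a single-state trace gives a FRET histogram
#' standard deviation of about 0.055.
#'
#' @param state_means FRET mean per state, strictly decreasing (R, RA, RAA).
#' @param total_intensity mean corrected total signal per frame (a.u.).
#' @param noise_sd per-channel additive Gaussian noise SD (a.u.).
#' @param crosstalk donor-to-acceptor leak fraction.
#' @param gamma detection-efficiency ratio applied to the donor channel.
#' @return An object of class `emission_params`.
#' @export
emission_params <- function(state_means = c(0.52, 0.40, 0.28),
                            total_intensity = 500,
                            noise_sd = 33.6,
                            crosstalk = 0.105,
                            gamma = 1.1) {
  stopifnot(is.numeric(state_means), length(state_means) >= 1)
  if (any(!is.finite(state_means))) stop("state_means must be finite")
  if (length(state_means) > 1 && any(diff(state_means) >= 0))
    stop("state_means must be strictly decreasing from R to RAA")
  if (crosstalk < 0 || crosstalk >= 1) stop("crosstalk must be in [0, 1)")
  if (gamma <= 0) stop("gamma must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (total_intensity <= 0) stop("total_intensity must be > 0")
  structure(list(state_means = state_means,
                 total_intensity = total_intensity,
                 noise_sd = noise_sd, crosstalk = crosstalk, gamma = gamma),
            class = "emission_params")
}

#' Photophysics parameters: photobleaching and background
#'
#' Donor and acceptor bleach times are drawn exponentially with the given
#' means; bleaching is rendered as a single instantaneous step. After the
#' acceptor bleaches the rendered FRET is ~0 with the donor persisting; after
#' the donor bleaches both channels fall to `background_level`.
#'
#' @param donor_bleach_mean mean donor bleach time (s).
#' @param acceptor_bleach_mean mean acceptor bleach time (s).
#' @param background_level post-bleach baseline (a.u.).
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(donor_bleach_mean = 80,
                                acceptor_bleach_mean = 120,
                                background_level = 0) {
  if (donor_bleach_mean <= 0 || acceptor_bleach_mean <= 0)
    stop("bleach means must be > 0")
  if (background_level < 0) stop("background_level must be >= 0")
  structure(list(donor_bleach_mean = donor_bleach_mean,
                 acceptor_bleach_mean = acceptor_bleach_mean,
                 background_level = background_level),
            class = "photophysics_params")
}

#' Molecule-selection criteria
#'
#' Criteria applied to candidate traces: single-step donor photobleaching,
#' no multi-step acceptor photobleaching, a stable total intensity before the
#' first bleach (coefficient of variation below `total_stability_cv_max`),
#' and at least `min_duration` seconds of usable FRET before the first
#' bleaching event.
#'
#' @param min_duration minimum usable FRET duration (s).
#' @param require_single_donor_bleach require exactly one donor bleach step.
#' @param require_single_acceptor_bleach reject traces with two or more
#'   acceptor bleach steps (an acceptor that outlives the donor shows none
#'   and is accepted).
#' @param total_stability_cv_max maximum coefficient of variation of the
#'   total intensity over the usable range.
#' @return An object of class `selection_criteria`.
#' @export
selection_criteria <- function(min_duration = 20,
                               require_single_donor_bleach = TRUE,
                               require_single_acceptor_bleach = TRUE,
                               total_stability_cv_max = 0.15) {
  if (min_duration <= 0) stop("min_duration must be > 0")
  if (total_stability_cv_max <= 0 || total_stability_cv_max >= 1)
    stop("total_stability_cv_max must be in (0, 1)")
  structure(list(min_duration = min_duration,
                 require_single_donor_bleach = require_single_donor_bleach,
                 require_single_acceptor_bleach = require_single_acceptor_bleach,
                 total_stability_cv_max = total_stability_cv_max),
            class = "selection_criteria")
}
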