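# Unit conventions used throughout: lengths in um, times in s,
# concentrations in uM. Gradient steepness g is accepted in 1/mm at all
# user-facing interfaces and converted to 1/um internally (factor 1e-3).

#' Avogadro-derived concentration conversion
#'
#' Number of molecules per cubic micrometer in a 1 uM solution
#' (6.02214e23 / L * 1e-15 L/um^3 * 1e-6 M).
#' @export
MOLECULES_PER_UM3_PER_UM <- 602.214

#' Diffusion-limited capture rate of a circular absorbing sensor
#'
#' Rate constant at which diffusing ligand molecules reach a perfectly
#' absorbing disk of radius `l`: 4*D*l in volume units, converted to
#' molecules per second per micromolar.
#'
#' @param D ligand diffusivity (um^2/s)
#' @param l sensor radius (um)
#' @param molecules_per_um3_per_uM conversion constant (molecules um^-3 uM^-1)
#' @return capture rate constant kD (s^-1 uM^-1)
#' @examples
#' diffusive_capture_rate(800, 0.06)  # ~1.2e5
#' @export
diffusive_capture_rate <- function(D, l,
                                   molecules_per_um3_per_uM = MOLECULES_PER_UM3_PER_UM) {
  if (!is.numeric(D) || !is.numeric(l) || any(D <= 0) || any(l <= 0)) {
    stop("diffusive_capture_rate(): D and l must be strictly positive")
  }
  4 * D * l * molecules_per_um3_per_uM
}

#' Physical constants of the molecule-arrival channel
#'
#' Container for the ligand diffusivity, sensor radius and the capture-rate
#' constant kD. By default kD is computed from first principles as
#' `diffusive_capture_rate(D, l)`; passing `kD` explicitly overrides this,
#' which is how rounded literature values (e.g. 1.2e5 s^-1 uM^-1) are
#' carried through calculations.
#'
#' @param D ligand diffusivity (um^2/s)
#' @param l sensor radius (um)
#' @param kD capture rate constant (s^-1 uM^-1); computed from D and l
#'   unless supplied
#' @param molecules_per_um3_per_uM conversion constant
#' @return an object of class `physical_constants`
#' @export
physical_constants <- function(D = 800, l = 0.06, kD = NULL,
                               molecules_per_um3_per_uM = MOLECULES_PER_UM3_PER_UM) {
  if (D <= 0 || l <= 0 || molecules_per_um3_per_uM <= 0) {
    stop("physical_constants(): all fields must be strictly positive")
  }
  if (is.null(kD)) {
    kD <- diffusive_capture_rate(D, l, molecules_per_um3_per_uM)
  } else if (kD <= 0) {
    stop("physical_constants(): kD must be strictly positive")
  }
  structure(list(D = D, l = l, kD = kD,
                 molecules_per_um3_per_uM = molecules_per_um3_per_uM),
            class = "physical_constants")
}

#' @export
print.physical_constants <- function(x, ...) {
  cat("Physical constants of the arrival channel\n")
  cat(sprintf("  D  = %g um^2/s, l = %g um\n", x$D, x$l))
  cat(sprintf("  kD = %.4g s^-1 uM^-1\n", x$kD))
  invisible(x)
}

#' Correlated-signal window factor
#'
#' Ratio (tau_v / T)^3 by which an information limit computed over
#' independent windows of duration `T` underestimates the limit for a
#' signal correlated over `tau_v` > T. The cubic power mirrors the tau_v^3
#' dependence of the arrival signal-to-noise ratio.
#'
#' @param tau_v signal correlation time (s)
#' @param T independent-window duration (s); must satisfy T < tau_v
#' @return dimensionless factor
#' @export
correlated_window_factor <- function(tau_v, T) {
  if (!(T > 0) || !(tau_v > T)) {
    stop("correlated_window_factor() assumes tau_v > T > 0: the signal must ",
         "be correlated over a time longer than the averaging window")
  }
  (tau_v / T)^3
}

#' Berg-Purcell single-run threshold
#'
#' The classic argument that a cell must resolve the concentration change
#' within a single run translates, in terms of the arrival signal-to-noise
#' ratio, into the condition gamma_r > 16/3. Gradient climbing is possible
#' well below this threshold because displacement accumulates inference
#' over many runs.
#'
#' @param gamma_r dimensionless arrival SNR (>= 0)
#' @return TRUE iff gamma_r strictly exceeds 16/3
#' @export
berg_purcell_exceeds_threshold <- function(gamma_r) {
  if (any(gamma_r < 0)) stop("gamma_r must be non-negative")
  gamma_r > 16 / 3
}
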