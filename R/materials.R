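#' Material constants at 511 keV
#'
#' Linear attenuation coefficients and Compton interaction fractions of the
#' materials used by the phantoms and the detector, evaluated at the 511 keV
#' annihilation energy (single-energy transport; scattered photons keep the
#' 511 keV coefficients, which is adequate down to the 440 keV acceptance
#' window).  Values follow standard published attenuation tables: water
#' 0.0096/mm; polyethylene density-scaled by electrons per gram (0.94 g/mL,
#' Z/A 0.571 vs 0.555 for water) to 0.0093/mm; glass 0.022/mm;
#' lung-equivalent foam 0.3 x water; LYSO total 0.087/mm.
#'
#' @return data.frame with columns `name`, `density` (g/mL), `mu_511`
#'   (mm^-1) and `compton_fraction` (fraction of interactions that are
#'   Compton at 511 keV).
#' @export
materials_511 <- function() {
  data.frame(
    name = c("vacuum", "air", "water", "polyethylene", "glass", "lung", "lyso"),
    density = c(0, 0.0012, 1.0, 0.94, 2.5, 0.30, 7.25),
    mu_511 = c(0, 1.15e-5, 0.0096, 0.0093, 0.022, 0.00288, 0.087),
    compton_fraction = c(0, 0.998, 0.998, 0.999, 0.97, 0.998, 0.68),
    stringsAsFactors = FALSE
  )
}

#' Look up one material by name
#' @param name material name as listed by [materials_511()]
#' @return one-row data.frame
#' @export
material <- function(name) {
  m <- materials_511()
  row <- m[m$name == name, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop("unknown material '", name, "'; see materials_511()")
  }
  stopifnot(row$mu_511 >= 0, row$compton_fraction >= 0,
            row$compton_fraction <= 1)
  row
}

#' Compton scattering kinematics
#'
#' Scattered photon energy `E' = E / (1 + (E/511)(1 - cos theta))`; the
#' recoil electron carries `E - E'`.
#'
#' @param energy incident photon energy (keV)
#' @param costheta cosine of the scattering angle
#' @return scattered photon energy (keV)
#' @export
compton_energy <- function(energy, costheta) {
  energy / (1 + (energy / 511) * (1 - costheta))
}

#' Default physics model parameters
#'
#' The stand-in physics knobs of the event generator.  `p_full` is the
#' probability that a photon interacting in a monolithic crystal deposits
#' its full energy (photoelectric capture or Compton followed by
#' reabsorption of the scattered photon, which large monolithic slabs
#' recover for most multi-site events); the complement deposits a single
#' Klein-Nishina Compton electron energy and the scattered photon escapes.
#' `p_full` was calibrated once against the design-A centred-line-source
#' sensitivity and is frozen for every other measurement; see the methods
#' vignette.  Positron range is an exponential mixture with mean 0.6 mm
#' (F-18 in water); acolinearity is a 0.5 degree FWHM half-normal deviation
#' from back-to-back.  Both act only in `f18` emission mode.
#'
#' @param mode emission mode, `"back_to_back"` or `"f18"`
#' @param ... overrides of individual parameters
#' @return named list of physics parameters
#' @export
physics_model <- function(mode = c("back_to_back", "f18"), ...) {
  mode <- match.arg(mode)
  p <- list(
    p_full = 0.707,
    energy_resolution = 0.115,
    ctr_fwhm_ns = 0.2,
    mu_lyso = material("lyso")$mu_511,
    energy_cutoff = 50,
    acolinearity_fwhm_deg = 0.5,
    prange_w1 = 0.6,
    prange_m1 = 0.2,
    prange_m2 = 1.2,
    mode = if (mode == "f18") 1L else 0L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown physics parameters: ", paste(bad, collapse = ", "))
    p <- modifyList(p, dots)
  }
  p
}
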