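# Chiral-nematic (cholesteric) structure optics: photonic-bandgap wavelength
# from the helical pitch, and the pitch <-> cross-angle <-> layer-count
# relations behind the structural-colour blue-shift.

#' Chiral-nematic pitch/optics state
#'
#' @param refractive_index Average film refractive index n (default 1.55).
#' @param pitch Helical period P in nm (> 0): the distance over which the
#'   director rotates 360 degrees.
#' @param reflection_angle Reflection angle theta in degrees (0, 90];
#'   90 = normal incidence.
#' @param cross_angle Rotation alpha between adjacent nanocrystal layers in
#'   degrees (0, 180).
#' @param layer_spacing Centre-to-centre spacing d of adjacent layers in nm.
#' @return An object of class `pitch_model`.
#' @examples
#' pitch_model(pitch = 404)
#' @export
pitch_model <- function(refractive_index = 1.55, pitch,
                        reflection_angle = 90, cross_angle = 7,
                        layer_spacing = 3.8) {
  stopifnot(
    "pitch must be > 0" = pitch > 0,
    "reflection_angle must be in (0, 90]" =
      reflection_angle > 0 && reflection_angle <= 90,
    "cross_angle must be in (0, 180)" = cross_angle > 0 && cross_angle < 180,
    "layer_spacing must be > 0" = layer_spacing > 0
  )
  structure(
    list(refractive_index = refractive_index, pitch = pitch,
         reflection_angle = reflection_angle, cross_angle = cross_angle,
         layer_spacing = layer_spacing),
    class = "pitch_model"
  )
}

#' Photonic-bandgap wavelength of a cholesteric film
#'
#' lambda = n * P * sin(theta): the Bragg-like selective reflection
#' wavelength of a chiral-nematic helix with pitch P, average refractive
#' index n, at reflection angle theta. Linear in both n and P.
#'
#' @param model A [pitch_model()].
#' @return Wavelength in nm.
#' @examples
#' pbg_wavelength(pitch_model(pitch = 404))   # ~626 nm, red film
#' @export
pbg_wavelength <- function(model) {
  stopifnot(inherits(model, "pitch_model"))
  model$refractive_index * model$pitch * sin(model$reflection_angle * pi / 180)
}

#' Number of layers forming one helical period
#'
#' Adjacent nanocrystal layers rotate by the cross angle alpha, so a full
#' 360-degree turn of the director takes N = 360 / alpha layers. Strictly
#' decreasing in alpha: a larger cross angle means fewer layers per period.
#'
#' @param cross_angle Cross angle alpha in degrees (> 0), vectorised.
#' @return Layers per period (dimensionless).
#' @examples
#' layers_per_period(7)   # ~51 layers
#' @export
layers_per_period <- function(cross_angle) {
  if (any(cross_angle <= 0)) stop("cross_angle must be > 0", call. = FALSE)
  360 / cross_angle
}

#' Pitch from the layer-stacking picture
#'
#' P = (360 / alpha) * d: the helical period implied by N = 360/alpha layers
#' at centre-to-centre spacing d. Decreasing in alpha, increasing in d --
#' both a wider cross angle and tighter packing shorten the pitch, which is
#' the microscopic mechanism of the structural-colour blue-shift. Note this
#' single-dimer estimate is a mechanism diagnostic, not a prediction of the
#' film-scale pitch.
#'
#' @param cross_angle Cross angle in degrees (> 0), vectorised.
#' @param layer_spacing Layer spacing d in nm (> 0), vectorised.
#' @return Pitch in nm.
#' @examples
#' pitch_from_stacking(7, 3.8)   # ~195 nm
#' @export
pitch_from_stacking <- function(cross_angle, layer_spacing) {
  if (any(layer_spacing <= 0)) stop("layer_spacing must be > 0", call. = FALSE)
  layers_per_period(cross_angle) * layer_spacing
}

#' Blue-shift wavelength series from stacking trajectories
#'
#' Element-wise photonic-bandgap wavelengths for paired series of cross
#' angles and layer spacings, as along an additive-loading series. When the
#' cross angles are non-decreasing and the spacings non-increasing, the
#' wavelength sequence is non-increasing: the blue-shift contract.
#'
#' @param cross_angles Cross angles in degrees, one per series step.
#' @param spacings Layer spacings in nm, same length.
#' @param n Average refractive index.
#' @param theta Reflection angle in degrees.
#' @return Wavelengths in nm, one per step.
#' @examples
#' blueshift_series(c(5, 6, 7, 8), c(3.9, 3.85, 3.8, 3.75))
#' @export
blueshift_series <- function(cross_angles, spacings, n = 1.55, theta = 90) {
  if (length(cross_angles) != length(spacings)) {
    stop(sprintf("length mismatch: %d cross angles vs %d spacings",
                 length(cross_angles), length(spacings)), call. = FALSE)
  }
  n * pitch_from_stacking(cross_angles, spacings) * sin(theta * pi / 180)
}
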