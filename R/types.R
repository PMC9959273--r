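# Domain types: light S3 records with validation at construction.

#' Fundamental physical constants
#'
#' CODATA values for the constants entering the double-layer and Lifshitz
#' expressions. Immutable by convention: construct once, pass around.
#'
#' @return An object of class `physical_constants` with fields
#'   `faraday` (C/mol), `gas_constant` (J/(mol K)), `boltzmann` (J/K),
#'   `planck` (J s) and `vacuum_permittivity` (F/m).
#' @examples
#' physical_constants()$faraday
#' @export
physical_constants <- function() {
  structure(
    list(
      faraday = 96485.33212,
      gas_constant = 8.314462618,
      boltzmann = 1.380649e-23,
      planck = 6.62607015e-34,
      vacuum_permittivity = 8.8541878128e-12
    ),
    class = "physical_constants"
  )
}

#' Electrolyte medium description
#'
#' The solvent/electrolyte surrounding the interacting surfaces. Ionic
#' strength is in mol/m^3 (1 mol/m^3 = 1 mM), matching the SI form of the
#' Debye expression. Optical/static properties of the medium are carried for
#' the Hamaker calculation.
#'
#' @param rel_permittivity Relative permittivity of the medium (dimensionless,
#'   default 78.5: water at 25 degrees C).
#' @param ionic_strength Electrolyte concentration c0 in mol/m^3 (>= 0).
#' @param temperature Absolute temperature in K (default 298.15).
#' @param refractive_index Visible-light refractive index of the medium
#'   (default 1.333, water).
#' @param static_dielectric Static dielectric constant of the medium used in
#'   the zero-frequency Lifshitz term (default 80.1, water).
#' @return An object of class `medium`.
#' @examples
#' medium(ionic_strength = 1)   # 1 mM 1:1 electrolyte in water
#' @export
medium <- function(rel_permittivity = 78.5, ionic_strength = 0,
                   temperature = 298.15, refractive_index = 1.333,
                   static_dielectric = 80.1) {
  stopifnot(
    "temperature must be > 0" = is.numeric(temperature) && temperature > 0,
    "ionic_strength must be >= 0" = is.numeric(ionic_strength) && ionic_strength >= 0,
    "rel_permittivity must be > 1" = is.numeric(rel_permittivity) && rel_permittivity > 1
  )
  structure(
    list(
      rel_permittivity = rel_permittivity,
      ionic_strength = ionic_strength,
      temperature = temperature,
      refractive_index = refractive_index,
      static_dielectric = static_dielectric
    ),
    class = "medium"
  )
}

#' Colloid-probe geometry
#'
#' Sphere-plate geometry of the force measurement: a sample-coated silica
#' microsphere (radius `sphere_radius` nm) against a sample-coated flat
#' substrate. The default is the 10 um-diameter probe sphere, r = 5000 nm.
#'
#' @param sphere_radius Sphere radius in nm (> 0).
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(sphere_radius = 5000) {
  stopifnot("sphere_radius must be > 0" =
              is.numeric(sphere_radius) && length(sphere_radius) == 1L && sphere_radius > 0)
  structure(list(sphere_radius = sphere_radius), class = "probe_geometry")
}

#' DLVO parameter bundle for one interacting pair
#'
#' @param kappa Debye parameter (inverse screening length) in 1/nm (> 0).
#' @param z_const Electrostatic interaction constant Z in nN (>= 0).
#' @param hamaker Hamaker constant A_H in J (>= 0). Default 3.6e-21 J, the
#'   literature value for cellulose across water.
#' @param geometry A [probe_geometry()].
#' @return An object of class `dlvo_params`.
#' @examples
#' dlvo_params(kappa = 0.04125, z_const = 9.305e-3)
#' @export
dlvo_params <- function(kappa, z_const, hamaker = 3.6e-21,
                        geometry = probe_geometry()) {
  stopifnot(
    "kappa must be > 0" = is.numeric(kappa) && kappa > 0,
    "z_const must be >= 0" = is.numeric(z_const) && z_const >= 0,
    "hamaker must be >= 0" = is.numeric(hamaker) && hamaker >= 0,
    inherits(geometry, "probe_geometry")
  )
  structure(
    list(kappa = kappa, z_const = z_const, hamaker = hamaker,
         geometry = geometry),
    class = "dlvo_params"
  )
}

#' Inputs for the two-term Lifshitz Hamaker constant
#'
#' Media 1 and 2 are the interacting surfaces, medium 3 the intervening
#' solvent. `eps*` are static dielectric constants; `n*` visible-light
#' refractive indices; `nu_e` the main electronic absorption frequency in the
#' UV (Hz).
#'
#' @param eps1,eps2,eps3 Static dielectric constants (>= 1).
#' @param n1,n2,n3 Refractive indices (>= 1).
#' @param nu_e Main electronic absorption frequency in Hz (default 3.0e15,
#'   a typical UV value).
#' @param temperature Absolute temperature in K.
#' @return An object of class `hamaker_inputs`.
#' @export
hamaker_inputs <- function(eps1, eps2, eps3, n1, n2, n3,
                           nu_e = 3.0e15, temperature = 298.15) {
  stopifnot(
    "dielectric constants must be >= 1" = all(c(eps1, eps2, eps3) >= 1),
    "refractive indices must be >= 1" = all(c(n1, n2, n3) >= 1),
    "nu_e must be > 0" = nu_e > 0,
    "temperature must be > 0" = temperature > 0
  )
  structure(
    list(eps1 = eps1, eps2 = eps2, eps3 = eps3,
         n1 = n1, n2 = n2, n3 = n3,
         nu_e = nu_e, temperature = temperature),
    class = "hamaker_inputs"
  )
}

#' @export
print.dlvo_params <- function(x, ...) {
  cat(sprintf(
    "DLVO parameters: kappa = %.5g 1/nm, Z = %.4g nN, A_H = %.3g J, r = %g nm\n",
    x$kappa, x$z_const, x$hamaker, x$geometry$sphere_radius))
  invisible(x)
}
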