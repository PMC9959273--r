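# Sphere-plate DLVO forward model and the physical-constant calculators.
#
# Unit discipline: distances nm, forces nN, Hamaker constant J, potentials V,
# ionic strength mol/m^3, temperature K. SI conversions are internal.

# nN per (J * nm / nm^2): A[J]*r[nm]/D[nm]^2 = A*r/D^2 * 1e9 N = * 1e18 nN
.VDW_UNIT <- 1e18

check_distance <- function(distance) {
  if (!is.numeric(distance) || any(!is.finite(distance)) || any(distance <= 0)) {
    stop("distance must be strictly positive and finite (nm)", call. = FALSE)
  }
  distance
}

#' Electrostatic double-layer force, sphere-plate geometry
#'
#' F_EDL(D) = kappa * r * Z * exp(-kappa * D): the screened-Coulomb repulsion
#' between a sphere of radius r and a flat plate at surface separation D,
#' in the linearised (Derjaguin) superposition form. Strictly positive for
#' Z > 0 and strictly decreasing in D.
#'
#' @param params A [dlvo_params()] bundle (kappa in 1/nm, Z in nN, radius nm).
#' @param distance Surface-to-surface separation D in nm (> 0, vectorised).
#' @return Force in nN (repulsion positive).
#' @examples
#' p <- dlvo_params(kappa = 0.04125, z_const = 9.305e-3)
#' edl_force(p, 94.43)
#' @export
edl_force <- function(params, distance) {
  stopifnot(inherits(params, "dlvo_params"))
  D <- check_distance(distance)
  params$kappa * params$geometry$sphere_radius * params$z_const *
    exp(-params$kappa * D)
}

#' Van der Waals force, sphere-plate geometry
#'
#' F_VDW(D) = -A_H * r / (6 D^2): the non-retarded dispersion attraction
#' between sphere and plate. Always <= 0 under the repulsion-positive sign
#' convention; magnitude falls off as 1/D^2.
#'
#' @inheritParams edl_force
#' @return Force in nN (always <= 0).
#' @examples
#' p <- dlvo_params(kappa = 0.04125, z_const = 9.305e-3)
#' vdw_force(p, 10)   # about -0.03 nN
#' @export
vdw_force <- function(params, distance) {
  stopifnot(inherits(params, "dlvo_params"))
  D <- check_distance(distance)
  -params$hamaker * params$geometry$sphere_radius * .VDW_UNIT / (6 * D^2)
}

#' Net DLVO force
#'
#' The sum of the double-layer repulsion and the van der Waals attraction,
#' `edl_force(params, D) + vdw_force(params, D)`, exactly.
#'
#' @inheritParams edl_force
#' @return Force in nN (repulsion positive).
#' @export
dlvo_force <- function(params, distance) {
  edl_force(params, distance) + vdw_force(params, distance)
}

# analytic dF/dD in nN/nm, used by limit_distance and the empirical checks
dlvo_slope <- function(params, distance) {
  D <- check_distance(distance)
  -params$kappa^2 * params$geometry$sphere_radius * params$z_const *
    exp(-params$kappa * D) +
    params$hamaker * params$geometry$sphere_radius * .VDW_UNIT / (3 * D^3)
}

#' Debye parameter from ionic strength
#'
#' kappa = sqrt(2 F^2 c0 / (eps eps0 R T)), the inverse Debye screening
#' length of a 1:1 electrolyte, returned in 1/nm. For water at 25 C this
#' reproduces the textbook lambda_D = 0.304/sqrt(c[M]) nm rule.
#'
#' @param med A [medium()] with `ionic_strength` > 0 (mol/m^3).
#' @param constants A [physical_constants()] bundle.
#' @return Debye parameter kappa in 1/nm.
#' @examples
#' 1 / kappa_from_ionic_strength(medium(ionic_strength = 1))  # ~9.6 nm
#' @export
kappa_from_ionic_strength <- function(med, constants = physical_constants()) {
  stopifnot(inherits(med, "medium"), inherits(constants, "physical_constants"))
  if (med$ionic_strength <= 0) {
    stop("ionic_strength must be > 0: zero ionic strength gives an infinite screening length",
         call. = FALSE)
  }
  kappa_si <- sqrt(
    2 * constants$faraday^2 * med$ionic_strength /
      (med$rel_permittivity * constants$vacuum_permittivity *
         constants$gas_constant * med$temperature)
  )
  kappa_si * 1e-9   # 1/m -> 1/nm
}

#' Electrostatic interaction constant from the Stern-layer potential
#'
#' Z = 64 pi eps eps0 (RT/F)^2 tanh^2(F psi_delta / (4 R T)), returned in nN.
#' Z is an even function of the Stern potential (tanh^2) and saturates at
#' 64 pi eps eps0 (RT/F)^2 for large |psi_delta|.
#'
#' @param med A [medium()].
#' @param psi_delta Stern-layer potential in volts (finite; sign irrelevant).
#' @param constants A [physical_constants()] bundle.
#' @return Interaction constant Z in nN.
#' @examples
#' z_from_stern_potential(medium(), -0.0377)  # CNC-like Stern potential
#' @export
z_from_stern_potential <- function(med, psi_delta,
                                   constants = physical_constants()) {
  stopifnot(inherits(med, "medium"), inherits(constants, "physical_constants"),
            is.numeric(psi_delta), all(is.finite(psi_delta)))
  RT_F <- constants$gas_constant * med$temperature / constants$faraday
  z_si <- 64 * pi * med$rel_permittivity * constants$vacuum_permittivity *
    RT_F^2 * tanh(psi_delta / (4 * RT_F))^2
  z_si * 1e9   # N -> nN
}

#' Two-term Lifshitz Hamaker constant
#'
#' A_H for media 1 and 2 interacting across medium 3: the zero-frequency
#' (static dielectric) term plus the dispersion term over visible refractive
#' indices,
#' \deqn{A_H = \frac{3}{4} k T
#'   \frac{\epsilon_1-\epsilon_3}{\epsilon_1+\epsilon_3}
#'   \frac{\epsilon_2-\epsilon_3}{\epsilon_2+\epsilon_3}
#'  + \frac{3 h \nu_e}{8\sqrt{2}}
#'   \frac{(n_1^2-n_3^2)(n_2^2-n_3^2)}
#'        {\sqrt{n_1^2+n_3^2}\,\sqrt{n_2^2+n_3^2}\,
#'         (\sqrt{n_1^2+n_3^2}+\sqrt{n_2^2+n_3^2})}.}
#' Symmetric under swapping media 1 and 2, and identically zero for
#' index- and dielectric-matched media.
#'
#' @param inputs A [hamaker_inputs()] bundle.
#' @param constants A [physical_constants()] bundle.
#' @return Hamaker constant in J.
#' @examples
#' # cellulose-water-cellulose, order 1e-21..1e-20 J
#' hamaker_constant(hamaker_inputs(6.0, 6.0, 80.1, 1.56, 1.56, 1.333))
#' @export
hamaker_constant <- function(inputs, constants = physical_constants()) {
  stopifnot(inherits(inputs, "hamaker_inputs"),
            inherits(constants, "physical_constants"))
  zero_freq <- 0.75 * constants$boltzmann * inputs$temperature *
    ((inputs$eps1 - inputs$eps3) / (inputs$eps1 + inputs$eps3)) *
    ((inputs$eps2 - inputs$eps3) / (inputs$eps2 + inputs$eps3))
  s1 <- sqrt(inputs$n1^2 + inputs$n3^2)
  s2 <- sqrt(inputs$n2^2 + inputs$n3^2)
  dispersion <- (3 * constants$planck * inputs$nu_e / (8 * sqrt(2))) *
    (inputs$n1^2 - inputs$n3^2) * (inputs$n2^2 - inputs$n3^2) /
    (s1 * s2 * (s1 + s2))
  zero_freq + dispersion
}

#' Limit distance of the DLVO interaction
#'
#' The separation beyond which the DLVO force profile is effectively flat:
#' the largest D at which the magnitude of the analytic slope |dF/dD| equals
#' `slope_threshold`. Particles approaching each other in suspension stall
#' near this separation, so it proxies the equilibrium interparticle spacing.
#' Found by bracketed root finding on the analytic derivative, scanning
#' outward-in so the outermost crossing is returned.
#'
#' @param params A [dlvo_params()] with `z_const` > 0.
#' @param slope_threshold Slope magnitude defining "flat", in nN/nm (> 0).
#'   Default 1.8e-3 nN/nm.
#' @param d_range Search interval in nm (default c(0.5, 2000)).
#' @return Limit distance in nm.
#' @examples
#' p <- dlvo_params(kappa = 0.04125, z_const = 9.305e-3)
#' limit_distance(p)   # ~92 nm
#' @export
limit_distance <- function(params, slope_threshold = 1.8e-3,
                           d_range = c(0.5, 2000)) {
  stopifnot(inherits(params, "dlvo_params"))
  if (params$z_const <= 0) {
    stop("limit_distance requires z_const > 0", call. = FALSE)
  }
  if (!is.numeric(slope_threshold) || slope_threshold <= 0) {
    stop("slope_threshold must be > 0", call. = FALSE)
  }
  g <- function(D) abs(dlvo_slope(params, D)) - slope_threshold
  grid <- exp(seq(log(d_range[1]), log(d_range[2]), length.out = 4096L))
  vals <- g(grid)
  crossings <- which(vals[-length(vals)] * vals[-1] <= 0 & vals[-length(vals)] != 0)
  if (length(crossings) == 0L) {
    stop(sprintf(
      "no slope crossing of %.3g nN/nm found in [%g, %g] nm",
      slope_threshold, d_range[1], d_range[2]), call. = FALSE)
  }
  i <- crossings[length(crossings)]   # outermost crossing = largest D
  uniroot(g, lower = grid[i], upper = grid[i + 1L], tol = 1e-10)$root
}
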