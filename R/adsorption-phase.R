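# QCM-D Sauerbrey adsorption quantification, lyotropic phase-separation
# analysis (anisotropic fraction, C_a, C_i) and rheological classification.

#' QCM-D frequency-shift trace
#'
#' @param time Time in s.
#' @param delta_f Frequency shift in Hz (same length as `time`); adsorption
#'   drives it negative.
#' @param overtone Odd positive harmonic order (1 = 5 MHz fundamental).
#' @param sauerbrey_coeff Mass sensitivity C in ng/(cm^2 Hz); default 17.7,
#'   the standard value for a 5 MHz AT-cut crystal.
#' @return An object of class `qcm_trace`.
#' @export
qcm_trace <- function(time, delta_f, overtone = 1L, sauerbrey_coeff = 17.7) {
  stopifnot(
    "time and delta_f must have equal length" = length(time) == length(delta_f),
    "overtone must be odd and positive" = overtone >= 1 && overtone %% 2 == 1,
    "sauerbrey_coeff must be > 0" = sauerbrey_coeff > 0
  )
  structure(list(time = as.numeric(time), delta_f = as.numeric(delta_f),
                 overtone = as.integer(overtone),
                 sauerbrey_coeff = sauerbrey_coeff),
            class = "qcm_trace")
}

#' Phase-separation record at one concentration
#'
#' Height of the birefringent (anisotropic) lower phase and total suspension
#' height in a sealed cuvette after equilibration.
#'
#' @param concentration Suspension concentration in wt%.
#' @param aniso_height Height of the anisotropic phase (any length unit).
#' @param total_height Total suspension height (same unit, > 0).
#' @return An object of class `phase_record`.
#' @export
phase_record <- function(concentration, aniso_height, total_height) {
  stopifnot(
    "total_height must be > 0" = total_height > 0,
    "aniso_height must be within [0, total_height]" =
      aniso_height >= 0 && aniso_height <= total_height
  )
  structure(list(concentration = concentration, aniso_height = aniso_height,
                 total_height = total_height),
            class = "phase_record")
}

#' Rheology sweep (oscillatory or steady shear)
#'
#' @param omega Angular frequencies in rad/s (oscillatory mode).
#' @param g_prime,g_double_prime Storage and loss moduli in Pa (oscillatory).
#' @param shear_rate Shear rates in 1/s (steady mode).
#' @param viscosity Viscosities in Pa s (steady mode).
#' @return An object of class `rheo_sweep` with a `mode` field
#'   (`"oscillatory"` or `"steady"`).
#' @export
rheo_sweep <- function(omega = NULL, g_prime = NULL, g_double_prime = NULL,
                       shear_rate = NULL, viscosity = NULL) {
  if (!is.null(omega)) {
    stopifnot(
      "oscillatory sweep needs g_prime and g_double_prime" =
        !is.null(g_prime) && !is.null(g_double_prime),
      "oscillatory arrays must have equal length" =
        length(omega) == length(g_prime) && length(omega) == length(g_double_prime),
      "moduli and frequencies must be positive" =
        all(omega > 0) && all(g_prime > 0) && all(g_double_prime > 0)
    )
    structure(list(mode = "oscillatory", omega = omega, g_prime = g_prime,
                   g_double_prime = g_double_prime), class = "rheo_sweep")
  } else {
    stopifnot(
      "steady sweep needs shear_rate and viscosity" =
        !is.null(shear_rate) && !is.null(viscosity),
      "steady arrays must have equal length" =
        length(shear_rate) == length(viscosity),
      "rates and viscosities must be positive" =
        all(shear_rate > 0) && all(viscosity > 0)
    )
    structure(list(mode = "steady", shear_rate = shear_rate,
                   viscosity = viscosity), class = "rheo_sweep")
  }
}

#' Sauerbrey areal mass from a QCM-D trace
#'
#' Delta_m = -C * mean(Delta_f) / n over an equilibrium window: the rigid-film
#' mass-frequency relation for a quartz crystal, with C the crystal's mass
#' sensitivity and n the overtone order. Linear in the frequency shift and
#' inversely proportional to the overtone.
#'
#' @param trace A [qcm_trace()].
#' @param equilibrium_window Length-2 numeric `(t_start, t_end)` in s over
#'   which the plateau is averaged; default the final 20% of the trace.
#' @return Adsorbed areal mass in ng/cm^2 (positive for adsorption).
#' @export
sauerbrey_mass <- function(trace, equilibrium_window = NULL) {
  stopifnot(inherits(trace, "qcm_trace"))
  if (is.null(equilibrium_window)) {
    t_max <- max(trace$time)
    equilibrium_window <- c(t_max - 0.2 * (t_max - min(trace$time)), t_max)
  }
  inside <- trace$time >= equilibrium_window[1] &
    trace$time <= equilibrium_window[2]
  if (!any(inside)) {
    stop(sprintf("equilibrium window [%g, %g] s lies outside the trace [%g, %g] s",
                 equilibrium_window[1], equilibrium_window[2],
                 min(trace$time), max(trace$time)), call. = FALSE)
  }
  -trace$sauerbrey_coeff * mean(trace$delta_f[inside]) / trace$overtone
}

#' Specific adsorption per mass of coating
#'
#' Converts a Sauerbrey areal mass into adsorbate mass per gram of the
#' sensor coating. Scale-invariant: doubling both inputs leaves the result
#' unchanged.
#'
#' @param areal_mass Adsorbed areal mass in ng/cm^2.
#' @param coating_areal_mass Coating areal mass in ug/cm^2 (> 0). The
#'   default 7.77 ug/cm^2 is the CNC coating inferred from the published
#'   676 ng/cm^2 -> 87 mg/g conversion pair; it is an inferred quantity, not
#'   a measured one.
#' @return Specific adsorption in mg adsorbate per g coating.
#' @examples
#' specific_adsorption(676)   # ~87 mg/g
#' specific_adsorption(76)    # ~10 mg/g
#' @export
specific_adsorption <- function(areal_mass, coating_areal_mass = 7.77) {
  if (any(coating_areal_mass <= 0)) {
    stop("coating_areal_mass must be > 0", call. = FALSE)
  }
  # ng/cm^2 / (ug/cm^2) = 1e-3 g/g = mg/g
  areal_mass / coating_areal_mass
}

#' Anisotropic phase fraction
#'
#' Height of the birefringent phase divided by the total suspension height;
#' 0 is fully isotropic, 1 fully anisotropic (total birefringence).
#'
#' @param record A [phase_record()].
#' @return Fraction in `[0, 1]`.
#' @export
anisotropic_fraction <- function(record) {
  stopifnot(inherits(record, "phase_record"))
  record$aniso_height / record$total_height
}

#' Critical concentrations of the isotropic-anisotropic transition
#'
#' C_a is the lowest tested concentration at which the anisotropic phase has
#' appeared (fraction > `tol`); C_i the lowest at which it is complete
#' (fraction >= 1 - `tol`). When the data do not bracket a transition the
#' value is reported as a one-sided bound on the tested range.
#'
#' @param records List of [phase_record()]s sorted by concentration.
#' @param tol Fraction tolerance for "appeared"/"complete" (default 0.02).
#' @return A list with elements `c_a`, `c_i` (wt%), flags `c_a_bound`,
#'   `c_i_bound` (`"exact"`, `"below_range"` or `"above_range"`) and the
#'   fractions; bounds carry the nearest tested concentration as value.
#' @examples
#' recs <- gen_phase_series(7.5, 10, c(6, 7.5, 9), noise_sd = 0, seed = 1)
#' critical_concentrations(recs)$c_a   # 7.5
#' @export
critical_concentrations <- function(records, tol = 0.02) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, logical(1), "phase_record")))
  conc <- vapply(records, `[[`, numeric(1), "concentration")
  if (is.unsorted(conc, strictly = TRUE)) {
    stop("phase records must be sorted by strictly increasing concentration",
         call. = FALSE)
  }
  frac <- vapply(records, anisotropic_fraction, numeric(1))
  appeared <- which(frac > tol)
  complete <- which(frac >= 1 - tol)
  if (length(appeared) == 0L) {
    c_a <- max(conc); c_a_bound <- "above_range"
  } else if (appeared[1] == 1L) {
    c_a <- min(conc); c_a_bound <- "below_range"
  } else {
    c_a <- conc[appeared[1]]; c_a_bound <- "exact"
  }
  if (length(complete) == 0L) {
    c_i <- max(conc); c_i_bound <- "above_range"
  } else if (complete[1] == 1L) {
    c_i <- min(conc); c_i_bound <- "below_range"
  } else {
    c_i <- conc[complete[1]]; c_i_bound <- "exact"
  }
  list(c_a = c_a, c_a_bound = c_a_bound, c_i = c_i, c_i_bound = c_i_bound,
       concentration = conc, fraction = frac)
}

#' Gel vs liquid-like classification from an oscillatory sweep
#'
#' A suspension is classified `"gel"` when the storage modulus exceeds the
#' loss modulus at every sampled angular frequency (rigid-gel signature);
#' otherwise `"liquid_like"`, with the G'/G'' crossover frequency reported
#' (log-interpolated) when one exists inside the sweep. Invariant under
#' common rescaling of both moduli.
#'
#' @param sweep An oscillatory-mode [rheo_sweep()] with >= 2 points.
#' @return A list with `state` (`"gel"` or `"liquid_like"`) and
#'   `crossover_omega` (rad/s or `NA`).
#' @export
classify_gel <- function(sweep) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$mode != "oscillatory") {
    stop("classify_gel needs an oscillatory sweep", call. = FALSE)
  }
  if (length(sweep$omega) < 2L) {
    stop("sweep too narrow: need at least 2 frequencies", call. = FALSE)
  }
  ratio <- log(sweep$g_prime / sweep$g_double_prime)
  if (all(ratio > 0)) {
    return(list(state = "gel", crossover_omega = NA_real_))
  }
  cross <- which(ratio[-length(ratio)] * ratio[-1] < 0)
  omega_c <- if (length(cross)) {
    i <- cross[1]
    exp(approx(ratio[c(i, i + 1L)], log(sweep$omega[c(i, i + 1L)]),
               xout = 0)$y)
  } else NA_real_
  list(state = "liquid_like", crossover_omega = omega_c)
}

# three-segment log-log piecewise linear fit; returns slopes + breakpoints
segment_loglog <- function(x, y, min_pts = 4L) {
  lx <- log10(x); ly <- log10(y)
  n <- length(lx)
  best <- NULL
  sse_line <- function(i, j) {
    f <- lm(ly[i:j] ~ lx[i:j])
    c(sum(resid(f)^2), unname(coef(f)[2]))
  }
  for (b1 in seq.int(min_pts, n - 2L * min_pts + 1L)) {
    for (b2 in seq.int(b1 + min_pts, n - min_pts + 1L)) {
      s1 <- sse_line(1L, b1)
      s2 <- sse_line(b1 + 1L, b2)
      s3 <- sse_line(b2 + 1L, n)
      sse <- s1[1] + s2[1] + s3[1]
      if (is.null(best) || sse < best$sse) {
        best <- list(sse = sse, slopes = c(s1[2], s2[2], s3[2]),
                     breaks = c(10^lx[b1], 10^lx[b2]))
      }
    }
  }
  best
}

#' Liquid-crystal viscosity-profile classification
#'
#' Lyotropic liquid-crystal suspensions show a three-region steady-shear
#' profile: shear thinning at low rates, a weakly thinning middle plateau,
#' and thinning again at high rates. The sweep is segmented into three
#' log-log linear pieces (breakpoints by least squares) and classified by
#' the segment slopes: `"lc_three_region"` when the middle slope is
#' shallower than `mid_slope` and both outer slopes steeper than
#' `outer_slope`; `"newtonian_then_thinning"` when a leading plateau is
#' followed by thinning; otherwise `"simple_shear_thinning"`. Invariant to
#' vertical scaling of the viscosity.
#'
#' @param sweep A steady-mode [rheo_sweep()] spanning >= 3 decades of shear
#'   rate with >= 12 points.
#' @param mid_slope Upper bound on "very weak thinning" (default -0.2):
#'   middle slopes above it count as a plateau.
#' @param outer_slope Threshold for genuine thinning (default -0.4).
#' @return A list with `label`, the three `slopes` and the two `breakpoints`
#'   (1/s).
#' @export
lc_viscosity_regions <- function(sweep, mid_slope = -0.2, outer_slope = -0.4) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$mode != "steady") {
    stop("lc_viscosity_regions needs a steady-shear sweep", call. = FALSE)
  }
  decades <- log10(max(sweep$shear_rate) / min(sweep$shear_rate))
  if (decades < 3 || length(sweep$shear_rate) < 12L) {
    stop(sprintf("sweep too narrow: %.2g decades, %d points (need >= 3 decades, >= 12 points)",
                 decades, length(sweep$shear_rate)), call. = FALSE)
  }
  seg <- segment_loglog(sweep$shear_rate, sweep$viscosity)
  s <- seg$slopes
  label <- if (max(s) - min(s) < 0.15) {
    "simple_shear_thinning"                       # one power law throughout
  } else if (s[2] > mid_slope && s[1] < outer_slope && s[3] < outer_slope) {
    "lc_three_region"
  } else if (s[1] > mid_slope && s[3] < outer_slope) {
    "newtonian_then_thinning"
  } else {
    "simple_shear_thinning"
  }
  list(label = label, slopes = s, breakpoints = seg$breaks)
}

#' Kinetic-arrest (colour-suppression) flag
#'
#' A formulation suppresses chiral structural colour when it gels before the
#' anisotropic phase can appear: gelation concentration at or below C_a. A
#' boolean composition of [classify_gel()] over concentration-indexed sweeps
#' with [critical_concentrations()] of the matching phase series.
#'
#' @param gel_concentrations Concentrations (wt%) whose oscillatory sweeps
#'   classified as gel; the lowest is the gelation concentration. May be
#'   empty (no gelation observed -> not suppressing).
#' @param c_a Critical appearance concentration C_a in wt%.
#' @return A list with `suppressing` (logical), `gelation_concentration`
#'   and `c_a`.
#' @export
kinetic_arrest_flag <- function(gel_concentrations, c_a) {
  gc <- if (length(gel_concentrations)) min(gel_concentrations) else NA_real_
  list(suppressing = !is.na(gc) && gc <= c_a,
       gelation_concentration = gc, c_a = c_a)
}
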