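# Seeded generators emulating every instrument input the pipeline consumes:
# colloid-probe force curves, QCM-D adsorption traces, phase-separation
# series and rheology sweeps. All are bit-reproducible given (spec, seed)
# and leave the caller's RNG state untouched.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of a synthetic force curve
#'
#' Forward-model parameters plus the instrument artefacts the generator
#' emulates: additive Gaussian force noise, and a short-range exponential
#' contact artefact standing in for the unmodelled steric/adsorption
#' deviation seen at small separations.
#'
#' @param params A [dlvo_params()] bundle.
#' @param d_range Separation range in nm, ordered and positive.
#' @param n_points Number of evenly spaced samples (>= 32).
#' @param noise_sd Gaussian force noise sd in nN (default 2e-3, typical
#'   colloid-probe scatter).
#' @param contact_artifact_amplitude Amplitude of the short-range artefact in
#'   nN (default 0.5).
#' @param contact_decay Artefact decay length in nm (default 5).
#' @param seed Integer seed for the per-curve noise draw.
#' @param pair_label,location_id,replicate_id Curve metadata.
#' @return A list of class `force_curve_spec`.
#' @export
force_curve_spec <- function(params, d_range = c(2, 200), n_points = 256L,
                             noise_sd = 2e-3, contact_artifact_amplitude = 0.5,
                             contact_decay = 5, seed = 20230415L,
                             pair_label = "unknown", location_id = 1L,
                             replicate_id = 1L) {
  stopifnot(
    inherits(params, "dlvo_params"),
    "d_range must be positive and ordered" =
      length(d_range) == 2L && d_range[1] > 0 && d_range[1] < d_range[2],
    "n_points must be >= 32" = n_points >= 32L,
    "noise_sd must be >= 0" = noise_sd >= 0
  )
  structure(
    list(params = params, d_range = d_range, n_points = as.integer(n_points),
         noise_sd = noise_sd,
         contact_artifact_amplitude = contact_artifact_amplitude,
         contact_decay = contact_decay, seed = as.integer(seed),
         pair_label = pair_label, location_id = location_id,
         replicate_id = replicate_id),
    class = "force_curve_spec"
  )
}

#' Generate one synthetic approach force curve
#'
#' force(D) = dlvo_force(D) + a_c exp(-D / d_c) + N(0, noise_sd^2), on an
#' even distance grid. With zero noise and zero artefact this is the exact
#' forward model, and [loglinear_fit()] recovers the generating parameters
#' to numerical precision.
#'
#' @param spec A [force_curve_spec()].
#' @return A [force_curve()] tagged `extend`.
#' @examples
#' p <- dlvo_params(kappa = 0.04125, z_const = 9.305e-3)
#' cv <- gen_force_curve(force_curve_spec(p, noise_sd = 0,
#'                                        contact_artifact_amplitude = 0))
#' @export
gen_force_curve <- function(spec) {
  stopifnot(inherits(spec, "force_curve_spec"))
  D <- seq(spec$d_range[1], spec$d_range[2], length.out = spec$n_points)
  f <- dlvo_force(spec$params, D) +
    spec$contact_artifact_amplitude * exp(-D / spec$contact_decay)
  if (spec$noise_sd > 0) {
    f <- f + with_seed(spec$seed, rnorm(length(D), sd = spec$noise_sd))
  }
  force_curve(D, f, direction = "extend", pair_label = spec$pair_label,
              location_id = spec$location_id, replicate_id = spec$replicate_id,
              metadata = list(generator = "gen_force_curve", seed = spec$seed))
}

#' Generate the full multi-pair replicate suite
#'
#' One curve set covering every pair in the parameter table, `replicates`
#' curves per pair, emulating the 100-repeats-at-10-locations measurement
#' protocol: replicate r is assigned location (r - 1) %/% ceiling(reps/10) + 1.
#'
#' @param pairs Parameter table with columns `pair_label`, `kappa_nm1`,
#'   `z_nN` (default [reference_pairs()]).
#' @param replicates Curves per pair (>= 1).
#' @param seed Master seed; per-curve seeds are drawn from it.
#' @param hamaker,geometry Shared forward-model inputs.
#' @param ... Further arguments passed to [force_curve_spec()] (noise,
#'   artefact, grid).
#' @return A [curve_set()] with `replicates * nrow(pairs)` curves.
#' @export
gen_reference_suite <- function(pairs = reference_pairs(), replicates = 10L,
                                seed = 20230415L, hamaker = 3.6e-21,
                                geometry = probe_geometry(), ...) {
  stopifnot(replicates >= 1L)
  n_total <- nrow(pairs) * replicates
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_total))
  per_loc <- max(1L, ceiling(replicates / 10))
  curves <- vector("list", n_total)
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    params <- dlvo_params(pairs$kappa_nm1[i], pairs$z_nN[i], hamaker, geometry)
    for (r in seq_len(replicates)) {
      k <- k + 1L
      spec <- force_curve_spec(
        params, seed = seeds[k], pair_label = pairs$pair_label[i],
        location_id = (r - 1L) %/% per_loc + 1L,
        replicate_id = r, ...)
      curves[[k]] <- gen_force_curve(spec)
    }
  }
  curve_set(curves, metadata = list(generator = "gen_reference_suite",
                                    seed = seed, replicates = replicates))
}

#' Generate a synthetic QCM-D adsorption trace
#'
#' Emulates an adsorption experiment: a stable baseline, a saturating
#' adsorption transient, a rinse step, and a final plateau whose Sauerbrey
#' mass equals `plateau_mass * (1 - rinse_drop_fraction)`. The frequency
#' shift at overtone n for areal mass m is Delta_f = -m n / C.
#'
#' @param plateau_mass Pre-rinse plateau areal mass in ng/cm^2 (>= 0).
#' @param overtone Odd harmonic order.
#' @param noise_sd Gaussian Delta_f noise sd in Hz (default 0.2).
#' @param rinse_drop_fraction Fraction of the adsorbed mass removed by the
#'   rinse, in `[0, 1]`.
#' @param seed Integer seed.
#' @param sauerbrey_coeff Crystal mass sensitivity C in ng/(cm^2 Hz).
#' @param duration Trace length in s.
#' @param n_points Number of samples.
#' @return A [qcm_trace()]; the default equilibrium window of
#'   [sauerbrey_mass()] (final 20%) lies inside the final plateau.
#' @export
gen_qcm_trace <- function(plateau_mass, overtone = 1L, noise_sd = 0.2,
                          rinse_drop_fraction = 0, seed = 20230415L,
                          sauerbrey_coeff = 17.7, duration = 3600,
                          n_points = 720L) {
  stopifnot("plateau_mass must be >= 0" = plateau_mass >= 0,
            "rinse_drop_fraction must be in [0, 1]" =
              rinse_drop_fraction >= 0 && rinse_drop_fraction <= 1)
  t <- seq(0, duration, length.out = n_points)
  f_ads <- -plateau_mass * overtone / sauerbrey_coeff
  f_final <- -plateau_mass * (1 - rinse_drop_fraction) * overtone / sauerbrey_coeff
  t1 <- 0.2 * duration    # end of baseline / start of adsorption
  t2 <- 0.6 * duration    # rinse
  tau_ads <- 0.08 * duration
  tau_rinse <- 0.02 * duration
  df <- numeric(n_points)
  grow <- t > t1 & t <= t2
  df[grow] <- f_ads * (1 - exp(-(t[grow] - t1) / tau_ads))
  after <- t > t2
  f_at_rinse <- f_ads * (1 - exp(-(t2 - t1) / tau_ads))
  df[after] <- f_final + (f_at_rinse - f_final) * exp(-(t[after] - t2) / tau_rinse)
  if (noise_sd > 0) {
    df <- df + with_seed(seed, rnorm(n_points, sd = noise_sd))
  }
  qcm_trace(t, df, overtone = overtone, sauerbrey_coeff = sauerbrey_coeff)
}

#' Generate a synthetic phase-separation series
#'
#' Anisotropic fraction 0 below `c_a`, 1 at and above `c_i`, and a linear
#' ramp (starting at a small positive onset fraction, so the transition is
#' visible at `c_a` itself) in between, plus clipped Gaussian noise.
#'
#' @param c_a,c_i Appearance and completion concentrations in wt%
#'   (`c_a <= c_i`; equal gives a step).
#' @param concentrations Tested concentrations in wt%, ascending.
#' @param noise_sd Fraction noise sd (default 0.02); results are clipped to
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @param total_height Cuvette fill height (default 10, arbitrary units).
#' @param onset_fraction Fraction emitted at exactly `c_a` (default 0.05).
#' @return A list of [phase_record()]s sorted by concentration.
#' @export
gen_phase_series <- function(c_a, c_i, concentrations, noise_sd = 0.02,
                             seed = 20230415L, total_height = 10,
                             onset_fraction = 0.05) {
  stopifnot("c_a must be <= c_i" = c_a <= c_i)
  conc <- sort(concentrations)
  frac <- vapply(conc, function(cc) {
    if (cc < c_a) 0
    else if (cc >= c_i) 1
    else onset_fraction + (1 - onset_fraction) * (cc - c_a) / (c_i - c_a)
  }, numeric(1))
  if (noise_sd > 0) {
    frac <- frac + with_seed(seed, rnorm(length(frac), sd = noise_sd))
  }
  frac <- pmin(1, pmax(0, frac))
  lapply(seq_along(conc), function(i) {
    phase_record(conc[i], frac[i] * total_height, total_height)
  })
}

#' Generate a synthetic rheology sweep
#'
#' Parametric sweeps with the named qualitative structure, built so the
#' classifiers recover the generating label:
#' * `"gel"`: oscillatory, G' above G'' at every frequency, both weak power
#'   laws (rigid-gel signature);
#' * `"liquid_like"`: oscillatory, G'' above G' at low frequency with a
#'   crossover inside the sweep;
#' * `"lc_three_region"`: steady shear, log-log slopes approximately
#'   (-0.8, -0.1, -0.6) over five decades;
#' * `"simple"`: steady shear, one power law of slope -0.5.
#'
#' @param kind One of `"gel"`, `"liquid_like"`, `"lc_three_region"`,
#'   `"simple"`.
#' @param seed Integer seed.
#' @param noise_sd Multiplicative log-normal noise sd on the moduli /
#'   viscosity (default 0.02).
#' @param n_points Samples per sweep.
#' @return A [rheo_sweep()] in the matching mode.
#' @export
gen_rheo_sweep <- function(kind = c("gel", "liquid_like", "lc_three_region",
                                    "simple"),
                           seed = 20230415L, noise_sd = 0.02,
                           n_points = 30L) {
  kind <- match.arg(kind)
  jitter <- function(n) {
    if (noise_sd > 0) with_seed(seed, exp(rnorm(n, sd = noise_sd))) else rep(1, n)
  }
  if (kind %in% c("gel", "liquid_like")) {
    omega <- 10^seq(-1, 2, length.out = n_points)
    noise <- with_seed(seed, matrix(exp(rnorm(2L * n_points,
                                              sd = noise_sd)), ncol = 2L))
    if (kind == "gel") {
      gp <- 50 * omega^0.08 * noise[, 1]
      gpp <- 18 * omega^0.12 * noise[, 2]
    } else {
      gp <- 0.8 * omega^1.6 * noise[, 1]    # crossover near omega = 10
      gpp <- 4.0 * omega^0.9 * noise[, 2]
    }
    rheo_sweep(omega = omega, g_prime = gp, g_double_prime = gpp)
  } else {
    rate <- 10^seq(-2, 3, length.out = n_points)
    eta <- if (kind == "simple") {
      2 * rate^-0.5
    } else {
      # continuous log-log piecewise: slopes -0.8 / -0.1 / -0.6,
      # breakpoints at 0.5 and 50 1/s
      b1 <- 0.5; b2 <- 50
      s <- c(-0.8, -0.1, -0.6)
      a1 <- 10                      # eta at 1/s under segment 1 scaling
      eta1 <- a1 * rate^s[1]
      c2 <- a1 * b1^(s[1] - s[2])
      c3 <- c2 * b2^(s[2] - s[3])
      ifelse(rate < b1, eta1,
             ifelse(rate < b2, c2 * rate^s[2], c3 * rate^s[3]))
    }
    eta <- eta * jitter(n_points)
    rheo_sweep(shear_rate = rate, viscosity = eta)
  }
}
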