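# Independent oracles used across the suite. These never call the package
# code paths they check.

# Closed-form limit distance ignoring the VDW contribution:
# |dF/dD| = kappa^2 r Z e^(-kappa D) = s  =>  D = ln(kappa^2 r Z / s) / kappa
edl_only_limit_distance <- function(kappa, z, r, threshold) {
  log(kappa^2 * r * z / threshold) / kappa
}

# Textbook Debye length for a 1:1 electrolyte in water at 25 C, nm per
# concentration in mol/L
debye_length_textbook <- function(c_molar) 0.304 / sqrt(c_molar)

# Direct arithmetic evaluation of the sphere-plate forward model in nN,
# written out independently of the package internals
forward_force_nN <- function(kappa, z, r, A, D) {
  kappa * r * z * exp(-kappa * D) - A * r * 1e18 / (6 * D^2)
}

# Independent nonlinear least-squares fit of the full sphere-plate model on
# tail-restricted data (kappa, Z free; A fixed). Used as the estimation
# oracle against the log-linear pipeline.
nls_dlvo_oracle <- function(distance, force, r, A, start_kappa, start_z) {
  df <- data.frame(D = distance, f = force)
  fit <- minpack.lm::nlsLM(
    f ~ k * r * z * exp(-k * D) - A * r * 1e18 / (6 * D^2),
    data = df, start = list(k = start_kappa, z = start_z),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  as.list(coef(fit))
}

# A clean noiseless forward-model curve for a reference pair row
make_clean_curve <- function(kappa, z, pair_label = "unknown",
                             d_range = c(40, 200), n_points = 200L,
                             hamaker = 3.6e-21) {
  gen_force_curve(force_curve_spec(
    dlvo_params(kappa, z, hamaker = hamaker),
    d_range = d_range, n_points = n_points,
    noise_sd = 0, contact_artifact_amplitude = 0,
    pair_label = pair_label))
}
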