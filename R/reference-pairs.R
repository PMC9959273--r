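#' Reference DLVO parameters for the CNC pair series
#'
#' The bundled parameter set for the seven colloid-probe pairs studied in the
#' charge-regulation experiments: pure CNC against CNC, PAAS (sodium
#' polyacrylate) against CNC, and the CNC/COS (chitosan oligosaccharide)
#' composite series at 1.0-3.0 wt% loading. Columns give the zeta potentials
#' of probe and substrate coatings (mV), the measured mean limit distance and
#' its error limit (nm), the Debye parameter kappa (1/nm) and the interaction
#' constant Z (nN). These serve as generation parameters for the synthetic
#' suite and as the reference against which the fitting pipeline is validated.
#'
#' @return A data.frame with one row per pair.
#' @examples
#' reference_pairs()
#' @export
reference_pairs <- function() {
  data.frame(
    pair_label = c("PAAS-CNC", "CNC-CNC",
                   "CNC/COS_1.0-CNC/COS_1.0", "CNC/COS_1.5-CNC/COS_1.5",
                   "CNC/COS_2.0-CNC/COS_2.0", "CNC/COS_2.5-CNC/COS_2.5",
                   "CNC/COS_3.0-CNC/COS_3.0"),
    zeta_probe_mV = c(-56.6, -37.7, -34.6, -31.8, -29.2, -28.0, -26.5),
    zeta_substrate_mV = c(-38.5, -37.7, -34.6, -31.8, -29.2, -28.0, -26.5),
    limit_distance_nm = c(97.23, 94.43, 91.59, 89.96, 83.31, 78.48, 68.91),
    limit_distance_err_nm = c(5.78, 7.56, 3.79, 7.92, 5.17, 5.79, 6.97),
    kappa_nm1 = c(0.03966, 0.04125, 0.03823, 0.03980, 0.04416, 0.05182, 0.05844),
    z_nN = c(11.17e-3, 9.305e-3, 8.594e-3, 8.402e-3, 7.527e-3, 6.504e-3, 6.277e-3),
    stringsAsFactors = FALSE
  )
}
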