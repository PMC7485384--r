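#' Calibrated controller presets for this plant
#'
#' Reflex parameter sets re-identified for this package's plant (default
#' anthropometry, contact model and muscle geometry) by lexicographic PSO on
#' a generated 110-s perturbation signal, warm-started from the published
#' sets in [controller_preset()].  These are the parameter sets that keep
#' *this* model standing through the perturbations; the published sets were
#' identified on a different physics engine and anthropometry and are kept
#' as the literature reference.
#'
#' @param architecture `"base"`, `"length"` or `"force"`.
#' @param com_delay COM trigger delay (s) to attach.
#' @return an `sr_controller`.
#' @export
calibrated_preset <- function(architecture = c("base", "length", "force"),
                              com_delay = 0) {
  architecture <- match.arg(architecture)
  z <- calibrated_vectors()[[architecture]]
  vector_to_params(z, architecture, com_delay = com_delay)
}

# decision vectors in make_bounds() order (u0 x9, [g_ffb x9], [g_lfb x9,
# l_off x9], x_toe, x_heel, z_toe, z_heel); values from the calibration
# optimization recorded in the package sources.
calibrated_vectors <- function() {
  list(
    base = c(
      # u0
      0.416887, 0.063452, 0.049920, 0.452900, 0.013732, 0.302979, 0.553615,
      0.360882, 0.357809,
      # g_ffb
      -2.458429, -1.521969, 1.481523, -2.576144, -1.687300, 0.489112,
      2.266442, 1.355999, 0.470078,
      # g_lfb
      -0.401306, -2.210218, -0.354979, 0.035367, 0.790430, -2.098140,
      0.868471, -1.023481, -1.510664,
      # l_off
      0.974545, 0.482439, 0.509276, 0.533465, 0.448903, 0.652859, 0.509154,
      1.031729, 0.538841,
      # x_toe, x_heel, z_toe, z_heel
      0.099088, 0.081911, 0.001395, 0.802186
    ),
    length = c(
      # u0
      0.411431, 0.143820, 0.263354, 0.214008, 0.193000, 0.310737, 0.761085,
      0.395105, 0.199425,
      # g_lfb
      -1.299128, -1.991066, 0.637923, -0.304062, -1.061893, -0.822124,
      1.031864, -0.190265, -2.769479,
      # l_off
      0.963990, 0.569835, 0.364265, 0.356725, 0.641540, 0.879088, 0.672255,
      0.930672, 0.405161,
      # x_toe, x_heel, z_toe, z_heel
      0.092216, 0.096442, 0.149693, 0.346210
    ),
    force = c(
      # u0
      0.585449, 0.357334, 0.233193, 0.512700, 0.501193, 0.450633, 0.609608,
      0.820766, 0.583042,
      # g_ffb
      -1.067216, -2.196232, 0.217559, -0.668258, -1.538787, -1.226023,
      0.304179, 0.624057, -2.609825,
      # x_toe, x_heel, z_toe, z_heel
      0.098260, 0.047943, 0.447464, 0.234553
    )
  )
}
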