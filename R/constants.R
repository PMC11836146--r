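#' Injury-metric constants
#'
#' Bundles every constant used by the kinematic injury metrics, overridable
#' per call. Defaults:
#'
#' * BrIC per-axis critical angular velocities: 66.2, 59.1, 44.2 rad/s.
#' * UBrIC critical angular velocities 211, 171, 115 rad/s; critical angular
#'   accelerations 20.0, 10.3, 7.76 krad/s^2; exponent `r = 2`.
#' * HIC window: 15 ms.
#' * DAMAGE: scalar factor `beta = 2.9903`; 3-DOF lumped-parameter model with
#'   unit diagonal mass matrix, stiffness kxx = 32142, kyy = 23493,
#'   kzz = 16935, kxz = kzx = 1636.3 (x-z coupling; other off-diagonals 0),
#'   and stiffness-proportional damping C = 5.9148e-3 * K, transcribed from
#'   the published DAMAGE model. The closed-form unit tests for the
#'   integrator use synthetic single-axis configurations, so the pipeline's
#'   correctness does not rest on this transcription.
#'
#' @param bric_critical length-3 angular-velocity criticals (rad/s), axes x,y,z.
#' @param ubric_w_critical length-3 angular-velocity criticals (rad/s).
#' @param ubric_a_critical length-3 angular-acceleration criticals (krad/s^2).
#' @param ubric_r outer exponent of the printed UBrIC form.
#' @param hic_window HIC window length in ms.
#' @param damage_beta DAMAGE scalar factor.
#' @param damage_mass,damage_stiffness,damage_damping 3x3 matrices of the
#'   coupled oscillator; mass must be symmetric positive definite.
#' @return a named list of class `metric_constants`.
#' @export
metric_constants <- function(bric_critical = c(x = 66.2, y = 59.1, z = 44.2),
                             ubric_w_critical = c(x = 211, y = 171, z = 115),
                             ubric_a_critical = c(x = 20.0, y = 10.3, z = 7.76),
                             ubric_r = 2,
                             hic_window = 15,
                             damage_beta = 2.9903,
                             damage_mass = diag(3),
                             damage_stiffness = NULL,
                             damage_damping = NULL) {
  if (is.null(damage_stiffness)) {
    damage_stiffness <- matrix(
      c(
        32142, 0, 1636.3,
        0, 23493, 0,
        1636.3, 0, 16935
      ),
      nrow = 3, byrow = TRUE
    )
  }
  if (is.null(damage_damping)) {
    damage_damping <- 5.9148e-3 * damage_stiffness
  }
  for (m in list(damage_mass, damage_stiffness, damage_damping)) {
    if (!isTRUE(all.equal(m, t(m)))) {
      stop_parameter("DAMAGE matrices must be symmetric")
    }
  }
  if (any(eigen(damage_mass, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop_parameter("DAMAGE mass matrix must be positive definite")
  }
  structure(
    list(
      bric_critical = bric_critical,
      ubric_w_critical = ubric_w_critical,
      ubric_a_critical = ubric_a_critical,
      ubric_r = ubric_r,
      hic_window = hic_window,
      damage_beta = damage_beta,
      damage_mass = damage_mass,
      damage_stiffness = damage_stiffness,
      damage_damping = damage_damping
    ),
    class = "metric_constants"
  )
}
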