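# shared fixture builders; everything is generated in code, nothing on disk

canonical_time <- function(n = 600, duration = 30) {
  (seq_len(n) - 1) * duration / n
}

# record with given channel vectors, defaulting everything else to zero
make_record <- function(t = canonical_time(), helmet_id = "A",
                        location = "XRot", ax = 0, ay = 0, az = 0,
                        wx = 0, wy = 0, wz = 0) {
  zero <- numeric(length(t))
  as_chan <- function(v) if (length(v) == 1) zero + v else v
  kin_record(
    tibble::tibble(
      t = t,
      ax = as_chan(ax), ay = as_chan(ay), az = as_chan(az),
      wx = as_chan(wx), wy = as_chan(wy), wz = as_chan(wz)
    ),
    helmet_id = helmet_id, location = location
  )
}

# small generator config for ensemble-level tests (keeps runtimes modest)
small_config <- function(seed = 1, n_elements = 500, strain_n_t = 31, ...) {
  generator_config(
    seed = seed,
    mesh = list(
      n_elements = n_elements, wm_fraction = 0.4,
      cc_fraction = 0.05, cerebellum_fraction = 0.05, other_fraction = 0.05
    ),
    strain_n_t = strain_n_t,
    ...
  )
}

# deformation-gradient history (n_t x 3 x 3) from a list of 3x3 matrices
F_series_of <- function(mats) {
  out <- array(0, c(length(mats), 3, 3))
  for (i in seq_along(mats)) out[i, , ] <- mats[[i]]
  out
}

# single-element strain_sim from a list of 3x3 deformation gradients
sim_of <- function(mats, a0 = c(1, 0, 0), region = "white_matter",
                   time = NULL) {
  n_t <- length(mats)
  if (is.null(time)) time <- seq(0, 30, length.out = n_t)
  F <- array(0, c(1, n_t, 3, 3))
  for (i in seq_len(n_t)) F[1, i, , ] <- mats[[i]]
  strain_sim(
    F = F, time = time, region = region,
    fiber = matrix(a0 / sqrt(sum(a0^2)), 1, 3),
    helmet_id = "A", location = "XRot"
  )
}

rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(
    0, -axis[3], axis[2],
    axis[3], 0, -axis[1],
    -axis[2], axis[1], 0
  ), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_unit_vector <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

# random deformation gradient with guaranteed positive determinant:
# rotation times a modest symmetric stretch
random_F <- function(scale = 0.25) {
  repeat {
    S <- matrix(rnorm(9, sd = scale / 2), 3, 3)
    S <- (S + t(S)) / 2
    R <- rotation_about(random_unit_vector(), runif(1, 0, pi / 3))
    F <- R %*% (diag(3) + S)
    if (det(F) > 0.1) return(F)
  }
}
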