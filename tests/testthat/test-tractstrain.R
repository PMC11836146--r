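test_that("Green-Lagrange tensor matches hand-expanded cases", {
  expect_equal(green_lagrange(diag(3)), matrix(0, 3, 3))
  E <- green_lagrange(diag(c(1.2, 1, 1)))
  expect_equal(E[1, 1], 0.22)
  expect_equal(E[-1, -1], matrix(0, 2, 2))
  expect_equal(sum(abs(E)) - abs(E[1, 1]), 0)
  # simple shear F = I + 0.5 e1 x e2
  Fs <- diag(3)
  Fs[1, 2] <- 0.5
  Es <- green_lagrange(Fs)
  expect_equal(Es[1, 2], 0.25)
  expect_equal(Es[2, 2], 0.125)
  expect_equal(Es, t(Es))
  expect_error(green_lagrange(diag(c(-1, 1, 1))), class = "helmstrain_data_error")
})

test_that("principal-strain histories agree with closed forms and a cubic-root oracle", {
  # uniaxial stretch held: peak (lambda^2 - 1)/2
  hold <- sim_of(list(diag(3), diag(c(1.2, 1, 1)), diag(c(1.2, 1, 1))))
  expect_equal(attr(mps_history(hold$F[1, , , ]), "peak"), 0.22)
  # simple shear gamma = 0.5: (0.125 + sqrt(0.265625)) / 2
  Fs <- diag(3)
  Fs[1, 2] <- 0.5
  h <- mps_history(F_series_of(list(diag(3), Fs)))
  expect_equal(attr(h, "peak"), (0.125 + sqrt(0.265625)) / 2, tolerance = 1e-12)

  # random tensors: largest eigenvalue equals the characteristic-polynomial root
  eig_oracle <- function(E) {
    # det(E - x I) = -x^3 + tr x^2 - m2 x + det
    tr <- sum(diag(E))
    m2 <- sum(diag(E)[c(1, 1, 2)] * diag(E)[c(2, 3, 3)]) -
      E[1, 2]^2 - E[1, 3]^2 - E[2, 3]^2
    roots <- polyroot(c(det(E), -m2, tr, -1))
    max(Re(roots))
  }
  set.seed(31)
  for (k in 1:50) {
    F <- random_F()
    E <- green_lagrange(F)
    h <- mps_history(F_series_of(list(diag(3), F)))
    expect_equal(attr(h, "peak"), max(0, eig_oracle(E)), tolerance = 1e-9)
  }
})

test_that("deformed fiber direction is the normalised image of the reference fiber", {
  a0 <- c(1, 0, 0)
  expect_equal(realtime_fiber_direction(diag(3), a0), a0)
  a_obl <- c(1, 1, 0) / sqrt(2)
  expect_equal(
    realtime_fiber_direction(diag(c(1.2, 1, 1)), a_obl),
    c(1.2, 1, 0) / sqrt(2.44)
  )
  R <- rotation_about(c(0, 0, 1), 0.7)
  a_r <- realtime_fiber_direction(R, a_obl)
  expect_equal(a_r, as.numeric(R %*% a_obl))
})

test_that("tract strains reproduce the uniaxial-stretch projections", {
  mats <- list(diag(3), diag(c(1.2, 1, 1)))
  Fser <- F_series_of(mats)
  # fiber along the sole stretch axis
  h1 <- tract_strain_histories(Fser, c(1, 0, 0))
  expect_equal(unlist(h1[2, c("ton", "tpn", "tos", "tps")]),
    c(ton = 0.22, tpn = 0, tos = 0, tps = 0),
    tolerance = 1e-12
  )
  # fiber perpendicular to the stretch axis
  h2 <- tract_strain_histories(Fser, c(0, 1, 0))
  expect_equal(unlist(h2[2, c("ton", "tpn", "tos", "tps")]),
    c(ton = 0, tpn = 0.22, tos = 0, tps = 0.11),
    tolerance = 1e-12
  )
  # oblique fiber: the deformed-direction convention gives
  # 0.22 * 1.44 / 2.44, the reference convention 0.11 - they differ
  a_obl <- c(1, 1, 0) / sqrt(2)
  h3 <- tract_strain_histories(Fser, a_obl, realtime_fiber = TRUE)
  expect_equal(h3$ton[2], 0.22 * 1.44 / 2.44, tolerance = 1e-12)
  h3r <- tract_strain_histories(Fser, a_obl, realtime_fiber = FALSE)
  expect_equal(h3r$ton[2], 0.11, tolerance = 1e-12)
  # engineering-shear reporting doubles the two shear channels
  set.seed(5)
  Fr <- random_F()
  a0 <- random_unit_vector()
  ht <- tract_strain_histories(F_series_of(list(diag(3), Fr)), a0)
  he <- tract_strain_histories(F_series_of(list(diag(3), Fr)), a0,
    engineering_shear = TRUE
  )
  expect_equal(he$tos, 2 * ht$tos)
  expect_equal(he$tps, 2 * ht$tps)

  expect_error(
    tract_strain_histories(Fser, c(2, 0, 0)),
    class = "helmstrain_contract_error"
  )
})

test_that("rigid motion produces exactly zero strain in all five metrics", {
  R <- rotation_about(c(1, 2, -1), 0.9)
  sim <- sim_of(list(diag(3), R), a0 = c(1, 1, 1) / sqrt(3))
  pk <- strain_peak_table(sim)
  expect_equal(max(abs(unlist(pk[c("mps", "mton", "mtpn", "mtos", "mtps")]))),
    0,
    tolerance = 1e-12
  )
})

test_that("perpendicular strains match a dense direction-sampling oracle", {
  # oracle: sample many unit vectors perpendicular to the deformed fiber
  perp_oracle <- function(F, a0, n_dir = 1e4) {
    E <- green_lagrange(F)
    a <- realtime_fiber_direction(F, a0)
    ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * a) * a
    u <- u / sqrt(sum(u^2))
    v <- c(
      a[2] * u[3] - a[3] * u[2],
      a[3] * u[1] - a[1] * u[3],
      a[1] * u[2] - a[2] * u[1]
    )
    th <- seq(0, pi, length.out = n_dir)
    d1 <- outer(cos(th), u) + outer(sin(th), v) # n x 3, all perp to a
    d2 <- outer(-sin(th), u) + outer(cos(th), v) # rotated by 90 deg
    q1 <- rowSums((d1 %*% E) * d1)
    Ea <- as.numeric(E %*% a)
    list(
      tpn = max(q1),
      tos = max(abs(d1 %*% Ea)),
      tps = max(abs(rowSums((d1 %*% E) * d2)))
    )
  }
  set.seed(41)
  for (k in 1:100) {
    F <- random_F()
    a0 <- random_unit_vector()
    h <- tract_strain_histories(F_series_of(list(F)), a0)
    o <- perp_oracle(F, a0)
    expect_equal(h$tpn[1], o$tpn, tolerance = 1e-3)
    expect_equal(h$tos[1], o$tos, tolerance = 1e-3)
    expect_equal(h$tps[1], o$tps, tolerance = 1e-3)
  }
})

test_that("tract strains are invariant under rigid rotation of the configuration", {
  set.seed(43)
  for (k in 1:20) {
    F <- random_F()
    a0 <- random_unit_vector()
    R <- rotation_about(random_unit_vector(), runif(1, 0, pi))
    h <- tract_strain_histories(F_series_of(list(F)), a0)
    hr <- tract_strain_histories(
      F_series_of(list(R %*% F %*% t(R))),
      as.numeric(R %*% a0)
    )
    expect_equal(unlist(hr[1, -1]), unlist(h[1, -1]), tolerance = 1e-12)
  }
})

test_that("tract strains do not depend on the perpendicular basis choice", {
  # independent construction with a randomised perpendicular basis
  basis_oracle <- function(F, a0) {
    E <- green_lagrange(F)
    a <- realtime_fiber_direction(F, a0)
    repeat {
      w <- rnorm(3)
      w <- w - sum(w * a) * a
      if (sqrt(sum(w^2)) > 1e-3) break
    }
    e2 <- w / sqrt(sum(w^2))
    e3 <- c(
      a[2] * e2[3] - a[3] * e2[2],
      a[3] * e2[1] - a[1] * e2[3],
      a[1] * e2[2] - a[2] * e2[1]
    )
    Q <- cbind(a, e2, e3)
    Ep <- t(Q) %*% E %*% Q
    blk <- Ep[2:3, 2:3]
    ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
    c(
      ton = Ep[1, 1], tpn = max(ev),
      tos = sqrt(Ep[1, 2]^2 + Ep[1, 3]^2),
      tps = (max(ev) - min(ev)) / 2
    )
  }
  set.seed(47)
  for (k in 1:20) {
    F <- random_F()
    a0 <- random_unit_vector()
    h <- unlist(tract_strain_histories(F_series_of(list(F)), a0)[1, -1])
    o <- basis_oracle(F, a0)
    expect_equal(unname(h), unname(o), tolerance = 1e-12)
  }
})

test_that("accumulated peaks follow running-max semantics", {
  # pulse that loads then fully unloads: the peak is the mid-pulse value
  lam <- c(1, 1.1, 1.25, 1.1, 1)
  sim <- sim_of(lapply(lam, function(l) diag(c(l, 1, 1))), a0 = c(1, 0, 0))
  pk <- strain_peak_table(sim)
  expect_equal(pk$mps, (1.25^2 - 1) / 2)
  expect_equal(pk$mton, (1.25^2 - 1) / 2)
  # monotone loading peaks at the final time
  lam2 <- seq(1, 1.3, length.out = 5)
  sim2 <- sim_of(lapply(lam2, function(l) diag(c(l, 1, 1))), a0 = c(1, 0, 0))
  expect_equal(strain_peak_table(sim2)$mps, (1.3^2 - 1) / 2)
  # random histories: equals an independent sort-based max
  set.seed(51)
  mats <- c(list(diag(3)), lapply(1:6, function(i) random_F(0.15)))
  sim3 <- sim_of(mats, a0 = random_unit_vector())
  pk3 <- strain_peak_table(sim3)
  per_time <- vapply(mats, function(F) {
    max(eigen(green_lagrange(F), symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
  expect_equal(pk3$mps, sort(per_time, decreasing = TRUE)[1])
})

test_that("compressive-only fiber loading clamps the tract-normal peak at zero", {
  sim <- sim_of(list(diag(3), diag(c(0.9, 1, 1))), a0 = c(1, 0, 0))
  pk <- strain_peak_table(sim)
  expect_equal(pk$mton, 0)
  expect_equal(pk$mps, 0) # uniaxial compression: largest principal strain is 0
})

test_that("elements losing det F > 0 are flagged invalid and excluded", {
  F <- array(0, c(2, 2, 3, 3))
  F[1, 1, , ] <- diag(3)
  F[1, 2, , ] <- diag(c(1.1, 1, 1))
  F[2, 1, , ] <- diag(3)
  F[2, 2, , ] <- diag(c(-0.5, 1, 1)) # inverted element
  sim <- strain_sim(
    F = F, time = c(0, 1), region = c("brain", "brain"),
    helmet_id = "A", location = "XRot"
  )
  pk <- strain_peak_table(sim)
  expect_equal(pk$valid, c(TRUE, FALSE))
  expect_equal(attr(pk, "n_invalid"), 1)
  expect_equal(
    percentile_summary(pk$mps, mask = pk$valid),
    (1.1^2 - 1) / 2
  )
})

test_that("percentile summaries follow the interpolated order-statistic definition", {
  expect_equal(percentile_summary(1:100, 95), 95.05)
  expect_equal(percentile_summary(rep(3.2, 17)), 3.2)
  expect_equal(percentile_summary(c(4, 9, 1), 100), 9)
  expect_error(percentile_summary(numeric(0)), class = "helmstrain_data_error")
  # sort-and-interpolate oracle on random input
  set.seed(61)
  x <- rnorm(37)
  q <- 95
  k <- 1 + q / 100 * (length(x) - 1)
  xs <- sort(x)
  expected <- xs[floor(k)] + (k - floor(k)) * (xs[ceiling(k)] - xs[floor(k)])
  expect_equal(percentile_summary(x, q), expected)
})

test_that("region restriction partitions elements and preserves summaries", {
  cfg <- small_config(n_elements = 400)
  setup <- strain_field_setup(cfg)
  rec <- generate_kinematics_ensemble(cfg)[["A_XRot"]]
  pk <- strain_peak_table(generate_strain_sim(rec, setup, cfg))
  counts <- vapply(
    strain_regions(),
    function(rg) nrow(region_restrict(pk, rg)), numeric(1)
  )
  expect_equal(sum(counts), nrow(pk))
  expect_equal(unname(counts["corpus_callosum"]), round(0.05 * 400))
  expect_error(region_restrict(pk, "thalamus"), "known",
    class = "helmstrain_parameter_error"
  )
  # restriction to a full cover reproduces unrestricted summaries
  cc <- region_restrict(pk, "corpus_callosum")
  expect_true(all(cc$region == "corpus_callosum"))
  s_cc <- strain_summary(cc)
  expect_equal(
    s_cc$value[s_cc$metric == "MTON"],
    percentile_summary(cc$mton, mask = cc$valid & cc$is_wm)
  )
})

test_that("strain containers round-trip through the text format", {
  cfg <- small_config(n_elements = 250, strain_n_t = 7)
  setup <- strain_field_setup(cfg)
  rec <- generate_kinematics_ensemble(cfg)[["B_YRot"]]
  sim <- generate_strain_sim(rec, setup, cfg)
  stem <- file.path(withr::local_tempdir(), "sim")
  write_strain_sim(sim, stem)
  back <- read_strain_sim(stem)
  expect_equal(back$F, sim$F, tolerance = 1e-12)
  expect_equal(back$region, sim$region)
  expect_equal(back$fiber, sim$fiber, tolerance = 1e-12)
  expect_equal(back$time, sim$time)
  expect_equal(back$helmet_id, "B")
  expect_equal(
    strain_peak_table(back)$mps, strain_peak_table(sim)$mps,
    tolerance = 1e-12
  )
})
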