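test_that("peak resultant metrics match closed-form cases", {
  expect_equal(pla(make_record(ax = 10)), 10)
  expect_equal(pla(make_record(ax = 3, ay = 4)), 5)
  # sampled half-sine: peak within one sample's interpolation error
  t <- canonical_time()
  half <- ifelse(t <= 10, 120 * sin(pi * t / 10), 0)
  expect_equal(pla(make_record(ax = half)), 120, tolerance = 1e-4)

  t_closed <- seq(0, 30, by = 0.05) # closed grid so the ramp tops out at 30
  rec <- make_record(t = t_closed, wy = t_closed)
  expect_equal(pav(rec), 30)
  expect_equal(paa(derive_angular_acceleration(rec, filter_first = FALSE)),
    1.0,
    tolerance = 1e-6
  )
  zero <- make_record()
  expect_equal(pav(zero), 0)
  expect_equal(paa(derive_angular_acceleration(zero, filter_first = FALSE)), 0)

  # three-axis damped sinusoid equals a direct per-sample scan
  wx <- 20 * exp(-t / 10) * sin(2 * pi * t / 12)
  wy <- 15 * exp(-t / 8) * cos(2 * pi * t / 9)
  wz <- 10 * exp(-t / 15) * sin(2 * pi * t / 7)
  rec3 <- make_record(wx = wx, wy = wy, wz = wz)
  expect_equal(pav(rec3), max(sqrt(wx^2 + wy^2 + wz^2)))
})

test_that("HIC matches its closed forms and the exhaustive window search", {
  # constant 100 g over 30 ms: optimum is the full 15 ms window
  rec <- make_record(ax = 100)
  h <- hic(rec)
  expect_equal(as.numeric(h), 0.015 * 100^2.5, tolerance = 1e-9)
  expect_equal(diff(attr(h, "window")), 15, tolerance = 1e-9)
  expect_equal(as.numeric(hic(make_record())), 0)

  # brute-force all-pairs oracle, same trapezoid rule, exact agreement
  hic_oracle <- function(rec, window_ms = 15) {
    a <- sqrt(rec$ax^2 + rec$ay^2 + rec$az^2)
    t <- rec$t / 1000
    n <- length(a)
    inc <- (a[-1] + a[-n]) / 2 * diff(t)
    best <- 0
    for (i in 1:(n - 1)) {
      acc <- 0
      for (j in (i + 1):n) {
        dt <- t[j] - t[i]
        if (dt > window_ms / 1000 + 1e-12) break
        acc <- acc + inc[j - 1]
        v <- dt * (acc / dt)^2.5
        if (v > best) best <- v
      }
    }
    best
  }
  t <- canonical_time(240, 12)
  half <- ifelse(t <= 10, 150 * sin(pi * t / 10), 0)
  expect_equal(
    as.numeric(hic(make_record(t = t, ax = half))),
    hic_oracle(make_record(t = t, ax = half))
  )
  set.seed(11)
  for (k in 1:10) {
    rec_r <- make_record(
      t = t,
      ax = abs(rnorm(240, 40, 30)), ay = abs(rnorm(240, 20, 15)),
      az = abs(rnorm(240, 10, 10))
    )
    expect_equal(as.numeric(hic(rec_r)), hic_oracle(rec_r))
  }
})

test_that("BrIC hits its construction points", {
  t <- canonical_time()
  pulse <- sin(pi * t / 30)
  expect_equal(bric(make_record(wx = 66.2 * pulse)), 1.0)
  expect_equal(
    bric(make_record(wx = 66.2 * pulse, wy = 59.1 * pulse, wz = 44.2 * pulse)),
    sqrt(3)
  )
  expect_equal(
    bric(make_record(
      wx = 33.1 * pulse, wy = 29.55 * pulse, wz = 22.1 * pulse
    )),
    0.8660,
    tolerance = 1e-4
  )
})

# record with controlled per-axis peaks: angular velocity ramps linearly to
# W_i over t1_i seconds and holds, so the velocity peak is exactly W_i and
# the acceleration peak exactly W_i / t1_i
ubric_record <- function(W, t1) {
  t_s <- canonical_time() / 1000
  chans <- lapply(1:3, function(i) W[i] * pmin(t_s / t1[i], 1))
  rec <- make_record(wx = chans[[1]], wy = chans[[2]], wz = chans[[3]])
  derive_angular_acceleration(rec, filter_first = FALSE)
}

test_that("UBrIC reproduces the printed-form fixed points and limits", {
  # single axis, w* = 1, alpha* ~ 10.6: the exponential term vanishes
  expect_equal(ubric(ubric_record(c(211, 0, 0), c(0.001, 1, 1))), 1.0,
    tolerance = 1e-3
  )
  # alpha* = w* makes the bracket collapse to w*: w* = 0.5, alpha = 10000
  expect_equal(
    ubric(ubric_record(c(105.5, 0, 0), c(105.5 / 10000, 1, 1))),
    0.25,
    tolerance = 1e-3
  )
  # all three axes at w* = 1 with saturated alpha*: (1+1+1)^2
  crit <- c(211, 171, 115)
  expect_equal(
    ubric(ubric_record(crit, rep(0.001, 3))),
    9.0,
    tolerance = 1e-2
  )
  # original r-norm form: three saturated axes give 3^(1/2)
  expect_equal(
    ubric(ubric_record(crit, rep(0.001, 3)), original_form = TRUE),
    sqrt(3),
    tolerance = 1e-2
  )
  # zero angular velocity contributes nothing even with nonzero alpha
  expect_equal(ubric(make_record() |> derive_angular_acceleration()), 0)
})

test_that("UBrIC is monotone non-decreasing in each per-axis peak", {
  set.seed(21)
  for (rep in 1:20) {
    W <- runif(3, 10, 100)
    t1 <- runif(3, 0.002, 0.01)
    base <- ubric(ubric_record(W, t1))
    axis <- sample(1:3, 1)
    W2 <- W
    W2[axis] <- W2[axis] * (1 + runif(1, 0.05, 0.5))
    expect_gte(ubric(ubric_record(W2, t1)) + 1e-12, base)
  }
})

test_that("DAMAGE integrator matches closed-form oscillator responses", {
  beta <- 2.9903
  # zero input
  expect_equal(as.numeric(damage(make_record() |>
    derive_angular_acceleration(filter_first = FALSE))), 0)

  # undamped single-axis step: max displacement = twice the static deflection
  m <- 1
  kk <- 40000 # wn = 200 rad/s, half period ~ 15.7 ms < 30 ms
  const <- metric_constants(
    damage_mass = diag(c(m, 1, 1)),
    damage_stiffness = diag(c(kk, 1, 1)),
    damage_damping = diag(0, 3)
  )
  alpha0 <- 500 # rad/s^2 step
  t <- canonical_time()
  rec <- make_record(wx = alpha0 * t / 1000) # ramp velocity = step acceleration
  rec <- derive_angular_acceleration(rec, filter_first = FALSE)
  expect_equal(
    as.numeric(damage(rec, const)),
    beta * 2 * alpha0 * m / kk,
    tolerance = 0.005
  )

  # damped single-axis sinusoid off resonance: steady-state amplitude
  zeta <- 0.4
  wn <- 400
  cc <- 2 * zeta * wn * m
  const2 <- metric_constants(
    damage_mass = diag(c(m, 1, 1)),
    damage_stiffness = diag(c(m * wn^2, 1, 1)),
    damage_damping = diag(c(cc, 0, 0))
  )
  A <- 300
  Om <- 2 * pi * 20
  t_long <- canonical_time(4000, 200) # 200 ms so the transient dies out
  t_s <- t_long / 1000
  # angular velocity whose derivative is A sin(Om t)
  rec2 <- make_record(t = t_long, wx = A / Om * (1 - cos(Om * t_s)))
  rec2 <- derive_angular_acceleration(rec2, filter_first = FALSE)
  d <- damage(rec2, const2)
  hist <- attr(d, "history")
  steady <- max(abs(hist$d1[hist$t > 0.1]))
  expected <- m * A / sqrt((m * wn^2 - m * Om^2)^2 + (cc * Om)^2)
  expect_equal(steady, expected, tolerance = 0.01)

  expect_error(
    metric_constants(damage_mass = diag(c(-1, 1, 1))),
    class = "helmstrain_parameter_error"
  )
})

test_that("DAMAGE scales linearly with input amplitude", {
  t <- canonical_time()
  w <- 20 * sin(2 * pi * t / 14) * exp(-t / 12)
  r1 <- derive_angular_acceleration(make_record(wx = w, wy = 0.5 * w),
    filter_first = FALSE
  )
  r2 <- derive_angular_acceleration(make_record(wx = 2 * w, wy = w),
    filter_first = FALSE
  )
  expect_equal(as.numeric(damage(r2)), 2 * as.numeric(damage(r1)),
    tolerance = 1e-9
  )
})

test_that("BrIC and PAV are invariant under time reversal and axis sign flips", {
  t <- canonical_time()
  wx <- 30 * sin(pi * t / 25)
  wy <- -12 * sin(pi * t / 18)
  rec <- make_record(wx = wx, wy = wy)
  rev_rec <- make_record(wx = rev(wx), wy = rev(wy))
  expect_equal(pav(rev_rec), pav(rec))
  expect_equal(bric(rev_rec), bric(rec))
  # resultant-based metrics ignore single-axis sign flips
  ax <- 80 * sin(pi * t / 12)^2
  ay <- 30 * sin(pi * t / 9)
  r_pos <- make_record(ax = ax, ay = ay)
  r_neg <- make_record(ax = -ax, ay = ay)
  expect_equal(pla(r_neg), pla(r_pos))
  expect_equal(as.numeric(hic(r_neg)), as.numeric(hic(r_pos)))
})

test_that("metric tables have one row per impact and honest summaries", {
  recs <- generate_kinematics_ensemble(generator_config(seed = 3))
  tbl <- metric_table(recs)
  expect_equal(nrow(tbl), 51)
  expect_true(all(vapply(tbl[-(1:2)], is.numeric, logical(1))))
  expect_true(all(as.matrix(tbl[-(1:2)]) >= 0))
  expect_error(metric_table(c(recs, recs[1])), "duplicate",
    class = "helmstrain_data_error"
  )
  # single-record ensemble: SD reported as 0
  s1 <- metric_location_summary(metric_table(recs[1]))
  expect_true(all(s1$sd == 0))
  # range max equals a planted maximum (direct scan oracle)
  s <- metric_location_summary(tbl)
  expect_equal(
    s$max[s$location == "XRot" & s$metric == "PLA"],
    max(tbl$PLA[tbl$location == "XRot"])
  )
})
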