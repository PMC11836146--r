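#' Kinematic head-injury metrics
#'
#' The seven standard kinematic metrics computed from one impact's
#' 6-DOF head kinematics:
#'
#' * `pla()` — peak resultant linear acceleration (g);
#' * `hic()` — Head Injury Criterion over a sliding window (default 15 ms):
#'   `max (t2-t1) * [mean a over (t1,t2)]^2.5` with trapezoidal integration;
#' * `paa()` — peak resultant angular acceleration (reported in krad/s^2);
#' * `pav()` — peak resultant angular velocity (rad/s);
#' * `bric()` — root-sum-square of per-axis peak angular velocities divided by
#'   the per-axis critical values;
#' * `ubric()` — velocity-and-acceleration criterion combining per-axis peaks
#'   `w* = w_max/w_cr`, `a* = a_max/a_cr` as
#'   `{ sum_i [ w* + (a* - w*) exp(-a*/w*) ] }^r` with `r = 2`;
#' * `damage()` — a scalar factor times the peak displacement norm of a 3-DOF
#'   coupled oscillator driven by head angular acceleration.
#'
#' Per-axis peaks for BrIC/UBrIC are maxima of absolute value and may occur
#' at different instants. Metrics needing angular acceleration derive it via
#' [derive_angular_acceleration()] when the record lacks it.
#'
#' @param record a [kin_record()].
#' @param constants a [metric_constants()].
#' @name headmetrics
NULL

resultant <- function(record, cols) {
  sqrt(rowSums(as.matrix(record[cols])^2))
}

ensure_ang_acc <- function(record) {
  if (!all(c("aax", "aay", "aaz") %in% names(record))) {
    record <- derive_angular_acceleration(record)
  }
  record
}

#' @rdname headmetrics
#' @return `pla()`: peak resultant linear acceleration in g.
#' @export
pla <- function(record) {
  max(resultant(record, c("ax", "ay", "az")))
}

#' @rdname headmetrics
#' @return `hic()`: the HIC value (dimensionless), with the optimising window
#'   `(t1, t2)` in ms attached as attribute `"window"`.
#' @export
hic <- function(record, constants = metric_constants()) {
  a <- resultant(record, c("ax", "ay", "az"))
  t_s <- record$t / 1000
  n <- length(a)
  # cumulative trapezoid of a(t) dt
  I <- c(0, cumsum((a[-1] + a[-n]) / 2 * diff(t_s)))
  dt_s <- kin_dt(record) / 1000
  w_max <- max(1L, floor(constants$hic_window / 1000 / dt_s + 1e-9))
  best <- 0
  best_ij <- c(1L, 2L)
  for (d in seq_len(min(w_max, n - 1L))) {
    i <- seq_len(n - d)
    j <- i + d
    dtau <- t_s[j] - t_s[i]
    v <- (I[j] - I[i])^2.5 / dtau^1.5
    k <- which.max(v)
    if (v[k] > best) {
      best <- v[k]
      best_ij <- c(i[k], j[k])
    }
  }
  structure(best, window = record$t[best_ij])
}

#' @rdname headmetrics
#' @return `paa()`: peak resultant angular acceleration in krad/s^2.
#' @export
paa <- function(record) {
  record <- ensure_ang_acc(record)
  max(resultant(record, c("aax", "aay", "aaz"))) / 1000
}

#' @rdname headmetrics
#' @return `pav()`: peak resultant angular velocity in rad/s.
#' @export
pav <- function(record) {
  max(resultant(record, c("wx", "wy", "wz")))
}

axis_peaks <- function(record, cols) {
  vapply(cols, function(col) max(abs(record[[col]])), numeric(1))
}

#' @rdname headmetrics
#' @export
bric <- function(record, constants = metric_constants()) {
  w <- axis_peaks(record, c("wx", "wy", "wz"))
  sqrt(sum((w / constants$bric_critical)^2))
}

#' @rdname headmetrics
#' @param original_form if `TRUE`, use the r-norm form of the original
#'   criterion, `{ sum_i term_i^r }^(1/r)`, instead of the printed form
#'   `{ sum_i term_i }^r`.
#' @export
ubric <- function(record, constants = metric_constants(),
                  original_form = FALSE) {
  record <- ensure_ang_acc(record)
  w_star <- axis_peaks(record, c("wx", "wy", "wz")) / constants$ubric_w_critical
  a_star <- axis_peaks(record, c("aax", "aay", "aaz")) / 1000 /
    constants$ubric_a_critical
  # analytic limit: w* = 0 makes the bracket vanish ((a*-0) e^-Inf -> 0)
  term <- ifelse(
    w_star == 0, 0,
    w_star + (a_star - w_star) * exp(-a_star / w_star)
  )
  r <- constants$ubric_r
  if (original_form) sum(term^r)^(1 / r) else sum(term)^r
}

#' @rdname headmetrics
#' @return `damage()`: the metric value, with the displacement history
#'   (columns `t` in s and `d1, d2, d3`) attached as attribute `"history"`.
#' @export
damage <- function(record, constants = metric_constants()) {
  record <- ensure_ang_acc(record)
  M <- constants$damage_mass
  K <- constants$damage_stiffness
  C <- constants$damage_damping
  Minv <- solve(M)
  t_s <- record$t / 1000
  alpha <- as.matrix(record[c("aax", "aay", "aaz")])
  af <- list(
    approxfun(t_s, alpha[, 1], rule = 2),
    approxfun(t_s, alpha[, 2], rule = 2),
    approxfun(t_s, alpha[, 3], rule = 2)
  )
  deriv <- function(t, y, parms) {
    d <- y[1:3]
    v <- y[4:6]
    a_t <- c(af[[1]](t), af[[2]](t), af[[3]](t))
    acc <- Minv %*% (-C %*% v - K %*% d - M %*% a_t)
    list(c(v, as.numeric(acc)))
  }
  sol <- deSolve::ode(
    y = numeric(6), times = t_s, func = deriv, parms = NULL, method = "rk4"
  )
  d <- sol[, 2:4, drop = FALSE]
  norms <- sqrt(rowSums(d^2))
  if (max(norms) > 1e6) {
    stop_numerical("DAMAGE integration unstable (displacement norm > 1e6); use a smaller time step")
  }
  history <- tibble(t = t_s, d1 = d[, 1], d2 = d[, 2], d3 = d[, 3])
  structure(constants$damage_beta * max(norms), history = history)
}

#' Kinematic metric table for an ensemble
#'
#' One row per (helmet, location) with the seven kinematic metrics. Angular
#' acceleration is derived (filtered velocity, central differences) where
#' absent.
#'
#' @param records list of [kin_record()]s.
#' @param constants a [metric_constants()].
#' @return tibble with columns `helmet_id, location, PLA, HIC, PAA, PAV,
#'   BrIC, UBrIC, DAMAGE`.
#' @export
metric_table <- function(records, constants = metric_constants()) {
  out <- purrr::map_dfr(records, function(rec) {
    rec <- ensure_ang_acc(rec)
    tibble(
      helmet_id = attr(rec, "helmet_id"),
      location = attr(rec, "location"),
      PLA = pla(rec),
      HIC = as.numeric(hic(rec, constants)),
      PAA = paa(rec),
      PAV = pav(rec),
      BrIC = bric(rec, constants),
      UBrIC = ubric(rec, constants),
      DAMAGE = as.numeric(damage(rec, constants))
    )
  })
  dup <- out |>
    count(helmet_id, location) |>
    filter(n > 1)
  if (nrow(dup) > 0) {
    stop_data(sprintf(
      "duplicate (helmet, location): %s",
      paste(dup$helmet_id, dup$location, sep = "/", collapse = ", ")
    ))
  }
  out
}

#' Per-location summary of a metric table
#'
#' Mean, standard deviation, minimum and maximum of each metric per impact
#' location (the usual "mean +/- SD (range)" summary shape). SD of a single
#' record is reported as 0.
#'
#' @param table a [metric_table()] result (possibly with strain summary
#'   columns appended).
#' @return long tibble `location, metric, mean, sd, min, max`.
#' @export
metric_location_summary <- function(table) {
  table |>
    tidyr::pivot_longer(-c(helmet_id, location),
      names_to = "metric", values_to = "value"
    ) |>
    group_by(location, metric) |>
    summarise(
      mean = mean(value),
      sd = if (n() > 1) sd(value) else 0,
      min = min(value),
      max = max(value),
      .groups = "drop"
    )
}
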