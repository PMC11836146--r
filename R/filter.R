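#' Phaseless low-pass crash-signal filter
#'
#' Forward-backward (zero phase lag) 2nd-order Butterworth low-pass, i.e.
#' 2 poles per pass and 4 poles total, the standard treatment for crash-test
#' channels. DC gain is exactly 1; at `cutoff_hz` the two passes leave an
#' amplitude ratio of 0.5 (the square of a single -3 dB stage). Endpoints are
#' handled by odd (point-reflected) padding of length at least four filter
#' time constants, so short records do not ring at the edges.
#'
#' The default cutoff of 1000 Hz matches the SAE-style conditioning applied
#' to laboratory headform channels. For the channel-class reading of that
#' convention, [cfc_presets()] tabulates the usual channel frequency classes
#' and their -3 dB frequencies (1.65 x class).
#'
#' @param series numeric vector, uniformly sampled.
#' @param dt sample step in ms.
#' @param cutoff_hz low-pass cutoff in Hz; must be below Nyquist.
#' @return filtered numeric vector, same length.
#' @export
cfc_filter <- function(series, dt, cutoff_hz = 1000) {
  fs <- 1000 / dt # Hz
  nyq <- fs / 2
  if (!is.finite(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyq) {
    stop_parameter(sprintf(
      "cutoff_hz = %g must lie in (0, Nyquist = %g Hz)", cutoff_hz, nyq
    ))
  }
  n <- length(series)
  if (n < 3) stop_data("series too short to filter")
  # >= 4 time constants of the analogue prototype, in samples
  n_pad <- min(n - 1, max(ceiling(4 * fs / (2 * pi * cutoff_hz)), 12))
  front <- 2 * series[1] - series[seq(n_pad + 1, 2)]
  back <- 2 * series[n] - series[seq(n - 1, n - n_pad)]
  x <- c(front, series, back)
  bf <- signal::butter(2, cutoff_hz / nyq, type = "low")
  # offset each pass by its starting value so the zero-state transient of
  # the recursion vanishes (the filter has unit DC gain)
  pass <- function(z) {
    as.numeric(signal::filter(bf, z - z[1])) + z[1]
  }
  y <- pass(x)
  y <- rev(pass(rev(y)))
  y[seq(n_pad + 1, n_pad + n)]
}

#' Channel frequency class presets
#'
#' The crash-test channel classes and their nominal -3 dB cutoff frequencies
#' (1.65 times the class number), usable as `cutoff_hz` presets for
#' [cfc_filter()].
#'
#' @return tibble with columns `class` and `cutoff_hz`.
#' @export
cfc_presets <- function() {
  cls <- c(60, 180, 600, 1000)
  tibble(class = paste0("CFC", cls), cutoff_hz = 1.65 * cls)
}

#' Differentiate a uniformly sampled series
#'
#' Central differences in the interior, one-sided at the two ends. Time is in
#' ms but the derivative is returned per second (so rad/s in gives rad/s^2
#' out). Exact for polynomials up to degree 2 in the interior.
#'
#' @param series numeric vector or matrix (columns differentiated
#'   independently).
#' @param dt sample step in ms.
#' @return derivative, same shape as `series`, in input units per second.
#' @export
differentiate <- function(series, dt) {
  if (is.matrix(series) || is.data.frame(series)) {
    m <- as.matrix(series)
    out <- apply(m, 2, differentiate, dt = dt)
    dimnames(out) <- dimnames(m)
    return(out)
  }
  n <- length(series)
  if (n < 3) stop_data("need at least 3 samples to differentiate")
  dt_s <- dt / 1000
  d <- numeric(n)
  d[1] <- (series[2] - series[1]) / dt_s
  d[n] <- (series[n] - series[n - 1]) / dt_s
  idx <- 2:(n - 1)
  d[idx] <- (series[idx + 1] - series[idx - 1]) / (2 * dt_s)
  d
}

#' Derive angular acceleration for a record
#'
#' Angular acceleration is always derived from the recorded angular velocity
#' (never read from file), by central differences. By default the velocity is
#' low-pass filtered with [cfc_filter()] first; set `filter_first = FALSE` to
#' differentiate the raw channels.
#'
#' @param record a [kin_record()].
#' @param filter_first filter angular velocity before differentiating?
#' @param cutoff_hz cutoff for the pre-filter.
#' @return the record with `aax, aay, aaz` columns (rad/s^2) added/replaced.
#' @export
derive_angular_acceleration <- function(record, filter_first = TRUE,
                                        cutoff_hz = 1000) {
  dt <- kin_dt(record)
  for (ax in c("x", "y", "z")) {
    w <- record[[paste0("w", ax)]]
    if (filter_first) w <- cfc_filter(w, dt, cutoff_hz)
    record[[paste0("aa", ax)]] <- differentiate(w, dt)
  }
  record
}

#' Low-pass filter selected channels of a record
#'
#' @param record a [kin_record()].
#' @param channels column names to filter.
#' @param cutoff_hz cutoff in Hz.
#' @return the record with the named channels replaced by filtered versions.
#' @export
filter_record <- function(record,
                          channels = c("ax", "ay", "az", "wx", "wy", "wz"),
                          cutoff_hz = 1000) {
  dt <- kin_dt(record)
  for (col in channels) {
    record[[col]] <- cfc_filter(record[[col]], dt, cutoff_hz)
  }
  record
}
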