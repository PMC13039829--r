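## Synthetic electroretinogram traces. The waveform is built piecewise so
## that, at zero noise, the truth amplitudes are realised exactly on the
## sample grid: a negative a-lobe descending from baseline to -a_amplitude
## at flash + a_implicit, a positive b-lobe rising from the trough by
## b_amplitude at flash + b_implicit, then a slow relaxation. Only the
## amplitude/latency measurements are defined by the study; the lobe shapes
## are free provided the truth is realised exactly.

ERG_INTENSITY_RANGE <- c(0.622, 6.955)  # log photons / um^2, stimulus protocol

#' Specification of a synthetic ERG trace
#'
#' @param sampling_rate_hz samples per second.
#' @param duration_ms record length (ms).
#' @param flash_time_ms flash onset (ms from record start).
#' @param flash_intensity_log_photons_per_um2 stimulus strength; must lie in
#'   the protocol range 0.622 to 6.955 log photons/um^2.
#' @param a_amplitude_uV,a_implicit_ms magnitude of the negative deflection
#'   (baseline to trough) and its latency from the flash.
#' @param b_amplitude_uV,b_implicit_ms trough-to-peak magnitude of the
#'   positive deflection and its latency from the flash.
#' @param noise_sigma_uV additive Gaussian noise s.d.
#' @param adaptation "dark" or "light".
#' @param group group label carried on the trace.
#' @param seed integer seed.
#' @return object of class `erg_trace_spec`.
#' @export
erg_trace_spec <- function(sampling_rate_hz = 2000,
                           duration_ms = 500,
                           flash_time_ms = 100,
                           flash_intensity_log_photons_per_um2 = 6.3,
                           a_amplitude_uV = 200,
                           a_implicit_ms = 15,
                           b_amplitude_uV = 400,
                           b_implicit_ms = 60,
                           noise_sigma_uV = 0,
                           adaptation = c("dark", "light"),
                           group = "WT",
                           seed = 1L) {
  adaptation <- match.arg(adaptation)
  assert_num1(a_amplitude_uV, "a_amplitude_uV", 0)
  assert_num1(b_amplitude_uV, "b_amplitude_uV", 0)
  assert_num1(noise_sigma_uV, "noise_sigma_uV", 0)
  if (a_implicit_ms >= b_implicit_ms) {
    stop("'a_implicit_ms' must be smaller than 'b_implicit_ms'", call. = FALSE)
  }
  fi <- flash_intensity_log_photons_per_um2
  if (fi < ERG_INTENSITY_RANGE[1] || fi > ERG_INTENSITY_RANGE[2]) {
    stop(sprintf("flash intensity %.3f outside the stimulus protocol range [%.3f, %.3f] log photons/um^2",
                 fi, ERG_INTENSITY_RANGE[1], ERG_INTENSITY_RANGE[2]),
         call. = FALSE)
  }
  if (duration_ms <= flash_time_ms + b_implicit_ms) {
    stop("record duration is shorter than flash_time + b_implicit", call. = FALSE)
  }
  structure(list(sampling_rate_hz = sampling_rate_hz,
                 duration_ms = duration_ms,
                 flash_time_ms = flash_time_ms,
                 flash_intensity_log_photons_per_um2 = fi,
                 a_amplitude_uV = a_amplitude_uV,
                 a_implicit_ms = a_implicit_ms,
                 b_amplitude_uV = b_amplitude_uV,
                 b_implicit_ms = b_implicit_ms,
                 noise_sigma_uV = noise_sigma_uV,
                 adaptation = adaptation,
                 group = group,
                 seed = as.integer(seed)),
            class = "erg_trace_spec")
}

#' ERG trace container
#'
#' @param time_ms strictly increasing sample times (ms).
#' @param voltage_uV samples (uV).
#' @param flash_time_ms flash onset; must lie within the record.
#' @param flash_intensity_log_photons_per_um2 stimulus strength.
#' @param adaptation "dark" or "light".
#' @param group group label.
#' @export
erg_trace <- function(time_ms, voltage_uV, flash_time_ms,
                      flash_intensity_log_photons_per_um2 = NA_real_,
                      adaptation = "dark", group = NA_character_) {
  if (length(time_ms) != length(voltage_uV)) {
    stop("time and voltage must have equal length", call. = FALSE)
  }
  if (any(diff(time_ms) <= 0)) {
    stop("'time_ms' must be strictly increasing", call. = FALSE)
  }
  if (flash_time_ms < time_ms[1] || flash_time_ms > time_ms[length(time_ms)]) {
    stop("'flash_time_ms' must lie within the record", call. = FALSE)
  }
  structure(list(time_ms = time_ms, voltage_uV = voltage_uV,
                 flash_time_ms = flash_time_ms,
                 flash_intensity_log_photons_per_um2 =
                   flash_intensity_log_photons_per_um2,
                 adaptation = adaptation, group = group),
            class = "erg_trace")
}

#' Generate a synthetic ERG trace with exact truth
#'
#' At `noise_sigma_uV = 0` the minimum of the trace is exactly
#' `-a_amplitude_uV` at `flash_time + a_implicit` (snapped to the sample
#' grid) and the maximum after the trough exceeds the trough by exactly
#' `b_amplitude_uV` at `flash_time + b_implicit`.
#'
#' @param spec an [erg_trace_spec()].
#' @return list with `trace` (an [erg_trace()]) and `truth` (realised
#'   amplitudes and implicit times on the sample grid).
#' @export
make_erg_trace <- function(spec) {
  stopifnot(inherits(spec, "erg_trace_spec"))
  dt <- 1000 / spec$sampling_rate_hz
  time_ms <- seq(0, spec$duration_ms, by = dt)
  ## snap the flash and both implicit times to the sample grid so truth is
  ## realised exactly at sample points
  snap <- function(t) time_ms[which.min(abs(time_ms - t))]
  flash <- snap(spec$flash_time_ms)
  t_a <- snap(flash + spec$a_implicit_ms)
  t_b <- snap(flash + spec$b_implicit_ms)
  a_amp <- spec$a_amplitude_uV
  b_amp <- spec$b_amplitude_uV
  peak_v <- b_amp - a_amp

  v <- numeric(length(time_ms))
  seg_a <- time_ms > flash & time_ms <= t_a
  v[seg_a] <- -a_amp * (1 - cos(pi * (time_ms[seg_a] - flash) / (t_a - flash))) / 2
  seg_b <- time_ms > t_a & time_ms <= t_b
  v[seg_b] <- -a_amp +
    b_amp * (1 - cos(pi * (time_ms[seg_b] - t_a) / (t_b - t_a))) / 2
  seg_c <- time_ms > t_b
  ## relax toward 0 when the peak is positive, otherwise hold the peak value
  ## so the maximum stays (first) at t_b
  target <- min(0, peak_v)
  tau <- 60
  v[seg_c] <- target + (peak_v - target) * exp(-(time_ms[seg_c] - t_b) / tau)

  if (spec$noise_sigma_uV > 0) {
    v <- v + withr::with_seed(spec$seed,
                              stats::rnorm(length(v), 0, spec$noise_sigma_uV))
  }
  trace <- erg_trace(time_ms, v, flash,
                     spec$flash_intensity_log_photons_per_um2,
                     spec$adaptation, spec$group)
  truth <- list(a_amplitude_uV = a_amp,
                a_implicit_ms = t_a - flash,
                b_amplitude_uV = b_amp,
                b_implicit_ms = t_b - flash,
                b_a_ratio = if (a_amp > 0) b_amp / a_amp else NA_real_)
  list(trace = trace, truth = truth)
}
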