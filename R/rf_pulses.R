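#' Piecewise-constant RF pulse waveforms
#'
#' An `rf_waveform` is the executable form of a radiofrequency pulse: an
#' ordered list of piecewise-constant segments, each with an amplitude
#' (gamma*B1/2pi, in Hz), an RF phase (radians), a carrier frequency offset
#' (Hz, relative to the reference/water frame) and a duration (seconds).
#' Gaps (delays) are represented as zero-amplitude segments. The carrier
#' phase is referenced to the start of the waveform, so two contiguous
#' segments at the same carrier with equal phases form a phase-coherent
#' continuation.
#'
#' @param amplitude_hz numeric vector of segment amplitudes (gamma*B1/2pi, Hz),
#'   all `>= 0`.
#' @param phase_rad numeric vector of segment RF phases (radians).
#' @param carrier_offset_hz numeric vector of per-segment carrier offsets (Hz).
#' @param duration_s numeric vector of segment durations (seconds), all `> 0`.
#' @param nominal_angle_deg nominal on-resonance excitation angle of the full
#'   pulse (degrees). A zero nominal angle requires all amplitudes to be zero.
#' @return An object of class `rf_waveform` with elements `segments` (a
#'   data frame), `total_duration_s` and `nominal_angle_deg`.
#' @seealso [make_libre()], [make_we_11()], [make_fs_chess()],
#'   [make_hard_pulse()]
#' @export
rf_waveform <- function(amplitude_hz, phase_rad, carrier_offset_hz,
                        duration_s, nominal_angle_deg = NA_real_) {
  n <- length(amplitude_hz)
  stopifnot(length(phase_rad) == n, length(carrier_offset_hz) == n,
            length(duration_s) == n)
  if (any(!is.finite(duration_s)) || any(duration_s <= 0))
    stop("all segment durations must be finite and > 0")
  if (any(!is.finite(amplitude_hz)) || any(amplitude_hz < 0))
    stop("all segment amplitudes must be finite and >= 0")
  if (any(!is.finite(carrier_offset_hz)))
    stop("carrier offsets must be finite")
  if (!is.na(nominal_angle_deg) && nominal_angle_deg == 0 &&
      any(amplitude_hz > 0))
    stop("a zero nominal angle requires all amplitudes to be zero")
  segments <- data.frame(
    amplitude_hz = as.numeric(amplitude_hz),
    phase_rad = as.numeric(phase_rad),
    carrier_offset_hz = as.numeric(carrier_offset_hz),
    duration_s = as.numeric(duration_s)
  )
  structure(
    list(segments = segments,
         total_duration_s = sum(segments$duration_s),
         nominal_angle_deg = nominal_angle_deg),
    class = "rf_waveform"
  )
}

#' @export
print.rf_waveform <- function(x, ...) {
  cat(sprintf("<rf_waveform> %d segment(s), total %.4g ms, nominal angle %s deg\n",
              nrow(x$segments), x$total_duration_s * 1e3,
              format(x$nominal_angle_deg)))
  invisible(x)
}

deg2rad <- function(x) x * pi / 180

#' Optimal LIBRE excitation frequency for fat nulling
#'
#' The LIBRE pulse is a pair of rectangular sub-pulses played at a common
#' off-resonant carrier frequency `f_RF`. Complete fat nulling occurs when
#' the fat isochromat performs a full rotation about its effective field
#' during each sub-pulse, which ties the sub-pulse duration `tau` to the
#' carrier offset:
#' \deqn{\tau = \sqrt{1 - (\alpha/2\pi)^2} / (f_{RF} - f_{fat})}
#' with the excitation angle \eqn{\alpha} in radians. This function solves
#' that condition for `f_RF`.
#'
#' @param tau_s sub-pulse duration (seconds), `> 0`.
#' @param alpha_deg RF excitation angle (degrees), in `[0, 360)`.
#' @param f_fat_hz fat resonance frequency (Hz), e.g. -440 at 3 T.
#' @return Optimal RF excitation frequency `f_RF` (Hz).
#' @examples
#' solve_optimal_frf(1.1e-3, 10, -440)  # ~469 Hz
#' @export
solve_optimal_frf <- function(tau_s, alpha_deg, f_fat_hz) {
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (!is.finite(f_fat_hz)) stop("f_fat_hz must be finite")
  if (alpha_deg < 0 || alpha_deg >= 360)
    stop("alpha_deg must be in [0, 360)")
  x <- deg2rad(alpha_deg) / (2 * pi)  # alpha in full turns
  f_fat_hz + sqrt(1 - x^2) / tau_s
}

#' Optimal LIBRE sub-pulse duration for fat nulling
#'
#' Inverse of [solve_optimal_frf()]: given the carrier frequency, returns the
#' sub-pulse duration satisfying the fat-nulling condition.
#'
#' @param f_rf_hz RF excitation frequency (Hz); must exceed `f_fat_hz`.
#' @inheritParams solve_optimal_frf
#' @return Optimal sub-pulse duration (seconds).
#' @export
solve_optimal_tau <- function(f_rf_hz, alpha_deg, f_fat_hz) {
  if (alpha_deg < 0 || alpha_deg >= 360)
    stop("alpha_deg must be in [0, 360)")
  if (!is.finite(f_rf_hz) || !is.finite(f_fat_hz) || f_rf_hz <= f_fat_hz)
    stop("f_rf_hz must be finite and > f_fat_hz")
  x <- deg2rad(alpha_deg) / (2 * pi)
  sqrt(1 - x^2) / (f_rf_hz - f_fat_hz)
}

#' Construct a LIBRE pulse waveform
#'
#' Two contiguous rectangular sub-pulses of duration `tau_s` each, both at
#' carrier offset `f_rf_hz`. The amplitude is set so that the nominal
#' on-resonance rotation of the full pulse equals `alpha_deg`
#' (gamma*B1 * 2*tau = alpha). The second sub-pulse carries a relative phase
#' offset (default pi) with respect to a phase-coherent continuation of the
#' first.
#'
#' @param alpha_deg nominal RF excitation angle (degrees).
#' @param f_rf_hz RF excitation (carrier) frequency (Hz).
#' @param tau_s sub-pulse duration (seconds).
#' @param phase2_rad phase offset of the second sub-pulse (radians),
#'   in `[0, 2*pi)`; default `pi`.
#' @return An [rf_waveform] with two segments and total duration `2*tau_s`.
#' @examples
#' w <- make_libre(18, 479, 1.1e-3)
#' w$total_duration_s  # 2.2 ms
#' @export
make_libre <- function(alpha_deg, f_rf_hz, tau_s, phase2_rad = pi) {
  if (!is.finite(tau_s) || tau_s <= 0) stop("tau_s must be > 0")
  if (!is.finite(f_rf_hz)) stop("f_rf_hz must be finite")
  if (phase2_rad < 0 || phase2_rad >= 2 * pi)
    stop("phase2_rad must be in [0, 2*pi)")
  amp <- (alpha_deg / 360) / (2 * tau_s)   # alpha spread over both sub-pulses
  rf_waveform(amplitude_hz = c(amp, amp),
              phase_rad = c(0, phase2_rad),
              carrier_offset_hz = c(f_rf_hz, f_rf_hz),
              duration_s = c(tau_s, tau_s),
              nominal_angle_deg = alpha_deg)
}

#' Construct a binomial 1-180-1 water-excitation pulse
#'
#' Two on-resonance rectangular sub-pulses of angle `alpha/2` each, timed so
#' that fat accrues 180 degrees of phase between the sub-pulse centers and is
#' returned to the longitudinal axis by the second sub-pulse. The separation
#' is specified center-to-center; the inter-pulse gap is a zero-amplitude
#' segment of duration `separation_s - sub_duration_s`.
#'
#' @param alpha_deg nominal excitation angle (degrees).
#' @param sub_duration_s duration of each rectangular sub-pulse (seconds).
#' @param separation_s center-to-center sub-pulse separation (seconds);
#'   must be `>= sub_duration_s`.
#' @return An [rf_waveform] with three segments (pulse, gap, pulse) and total
#'   span `separation_s + sub_duration_s`.
#' @examples
#' w <- make_we_11(18, 0.5e-3, 1.1e-3)  # 1.6 ms total span, 0.6 ms gap
#' @export
make_we_11 <- function(alpha_deg, sub_duration_s = 0.5e-3,
                       separation_s = 1.1e-3) {
  if (!is.finite(sub_duration_s) || sub_duration_s <= 0)
    stop("sub_duration_s must be > 0")
  if (separation_s < sub_duration_s)
    stop("invalid timing: separation_s must be >= sub_duration_s (center-to-center)")
  amp <- (alpha_deg / 360) / (2 * sub_duration_s)  # alpha/2 per sub-pulse
  gap <- separation_s - sub_duration_s
  if (gap == 0) {
    w <- rf_waveform(amplitude_hz = c(amp, amp), phase_rad = c(0, 0),
                     carrier_offset_hz = c(0, 0),
                     duration_s = c(sub_duration_s, sub_duration_s),
                     nominal_angle_deg = alpha_deg)
  } else {
    w <- rf_waveform(amplitude_hz = c(amp, 0, amp), phase_rad = c(0, 0, 0),
                     carrier_offset_hz = c(0, 0, 0),
                     duration_s = c(sub_duration_s, gap, sub_duration_s),
                     nominal_angle_deg = alpha_deg)
  }
  w
}

#' Construct a CHESS (fat-saturation) Gaussian prepulse
#'
#' A Gaussian-envelope pulse played at a frequency offset on the fat
#' resonance, discretized into piecewise-constant segments. The envelope is
#' truncated at +/- 2.5 standard deviations (sigma = duration/5) and the
#' amplitude is normalized so that the on-(carrier)-resonance integral
#' rotation equals `angle_deg`.
#'
#' @param angle_deg saturation flip angle (degrees), e.g. 110.
#' @param duration_s total pulse duration (seconds), e.g. 5.12e-3.
#' @param offset_hz carrier frequency offset (Hz), e.g. -407.
#' @param n_segments number of piecewise-constant segments (>= 64 recommended).
#' @return An [rf_waveform] of total duration `duration_s`.
#' @export
make_fs_chess <- function(angle_deg, duration_s = 5.12e-3, offset_hz = -407,
                          n_segments = 64) {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (n_segments < 2) stop("n_segments must be >= 2")
  sigma <- duration_s / 5  # truncation at +/- 2.5 sigma
  tt <- (seq_len(n_segments) - 0.5) / n_segments * duration_s
  env <- exp(-(tt - duration_s / 2)^2 / (2 * sigma^2))
  dt <- duration_s / n_segments
  # normalize integral rotation: sum(2*pi*amp*dt) = angle in radians
  amp <- env / (sum(env) * dt) * (angle_deg / 360)
  rf_waveform(amplitude_hz = amp,
              phase_rad = rep(0, n_segments),
              carrier_offset_hz = rep(offset_hz, n_segments),
              duration_s = rep(dt, n_segments),
              nominal_angle_deg = angle_deg)
}

#' Construct a rectangular on-resonance (hard) excitation pulse
#'
#' @param alpha_deg excitation angle (degrees); `gamma*B1*duration = alpha`.
#' @param duration_s pulse duration (seconds).
#' @return An [rf_waveform] with a single segment.
#' @examples
#' make_hard_pulse(18, 0.3e-3)$segments$amplitude_hz  # 166.67 Hz
#' @export
make_hard_pulse <- function(alpha_deg, duration_s = 0.3e-3) {
  if (!is.finite(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  amp <- (alpha_deg / 360) / duration_s
  rf_waveform(amplitude_hz = amp, phase_rad = 0, carrier_offset_hz = 0,
              duration_s = duration_s, nominal_angle_deg = alpha_deg)
}

#' Export / import waveforms as CSV or JSON
#'
#' The CSV layout has one row per segment with columns `start_time_s`,
#' `duration_s`, `amplitude_hz`, `phase_rad`, `carrier_offset_hz`.
#'
#' @param w an [rf_waveform].
#' @param path file path.
#' @return `waveform_write_csv`/`waveform_write_json` return `path`
#'   invisibly; the readers return an [rf_waveform].
#' @export
waveform_write_csv <- function(w, path) {
  stopifnot(inherits(w, "rf_waveform"))
  s <- w$segments
  out <- data.frame(start_time_s = cumsum(c(0, s$duration_s[-nrow(s)])),
                    duration_s = s$duration_s,
                    amplitude_hz = s$amplitude_hz,
                    phase_rad = s$phase_rad,
                    carrier_offset_hz = s$carrier_offset_hz)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname waveform_write_csv
#' @export
waveform_read_csv <- function(path) {
  d <- utils::read.csv(path)
  rf_waveform(d$amplitude_hz, d$phase_rad, d$carrier_offset_hz, d$duration_s)
}

#' @rdname waveform_write_csv
#' @export
waveform_write_json <- function(w, path) {
  stopifnot(inherits(w, "rf_waveform"))
  jsonlite::write_json(
    list(nominal_angle_deg = w$nominal_angle_deg, segments = w$segments),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname waveform_write_csv
#' @export
waveform_read_json <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  s <- d$segments
  rf_waveform(s$amplitude_hz, s$phase_rad, s$carrier_offset_hz, s$duration_s,
              nominal_angle_deg = if (is.null(d$nominal_angle_deg)) NA_real_
                                  else d$nominal_angle_deg)
}
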