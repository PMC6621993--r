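#' Tissue relaxation parameters
#'
#' @param T1_s longitudinal relaxation time (seconds); may be `Inf`.
#' @param T2_s transverse relaxation time (seconds); `T1_s >= T2_s > 0`.
#' @param f_hz resonance offset of the tissue in the reference frame (Hz);
#'   chemical shift plus any local field inhomogeneity.
#' @param M0 equilibrium magnetization (dimensionless), `> 0`.
#' @return An object of class `tissue_params`.
#' @examples
#' blood <- tissue_params(1.932, 0.275)         # myocardial blood at 3 T
#' fat   <- tissue_params(0.290, 0.100, -440)   # lipid pool at 3 T
#' @export
tissue_params <- function(T1_s, T2_s, f_hz = 0, M0 = 1) {
  if (!(T2_s > 0) || T1_s < T2_s)
    stop("require T1_s >= T2_s > 0")
  if (!is.finite(f_hz)) stop("f_hz must be finite")
  if (!(M0 > 0)) stop("M0 must be > 0")
  structure(list(T1_s = T1_s, T2_s = T2_s, f_hz = f_hz, M0 = M0),
            class = "tissue_params")
}

#' @export
print.tissue_params <- function(x, ...) {
  cat(sprintf("<tissue_params> T1=%.4g s, T2=%.4g s, f=%.4g Hz, M0=%.3g\n",
              x$T1_s, x$T2_s, x$f_hz, x$M0))
  invisible(x)
}

# right-hand rotation matrix about +z
rot_z <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

# right-hand rotation about unit axis u by angle theta (Rodrigues)
rot_axis <- function(u, theta) {
  c <- cos(theta); s <- sin(theta)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c + s * ux + (1 - c) * (u %o% u)
}

#' Affine propagator of an RF waveform for one tissue
#'
#' Precomputes the action of a full [rf_waveform] on a magnetization vector
#' as an affine map `m -> A %*% m + b` in the reference rotating frame.
#' Each non-zero segment is a pure rotation about its effective field
#' (evaluated in the frame co-rotating with the segment carrier, with
#' longitudinal component `f_tissue - carrier_offset`); relaxation is not
#' applied during RF segments. Zero-amplitude (gap) segments apply free
#' precession with relaxation (switchable). The carrier phase is referenced
#' to the waveform start, making the propagator invariant to subdividing any
#' rectangular segment.
#'
#' The rotation convention is `dM/dt = gamma * M x B`: a 90-degree
#' on-resonance pulse along +x takes (0,0,1) to (0,1,0).
#'
#' @param w an [rf_waveform].
#' @param tissue a [tissue_params].
#' @param relax_gaps apply T1/T2 relaxation during zero-amplitude segments
#'   (default `TRUE`).
#' @return list with `A` (3x3 matrix) and `b` (length-3 offset).
#' @export
pulse_propagator <- function(w, tissue, relax_gaps = TRUE) {
  stopifnot(inherits(w, "rf_waveform"), inherits(tissue, "tissue_params"))
  A <- diag(3)
  b <- c(0, 0, 0)
  ft <- tissue$f_hz
  t0 <- 0
  s <- w$segments
  for (i in seq_len(nrow(s))) {
    a <- s$amplitude_hz[i]; fc <- s$carrier_offset_hz[i]
    ph <- s$phase_rad[i]; d <- s$duration_s[i]
    if (a == 0) {
      # gap: free precession about z (carrier drops out), optional relaxation
      S <- rot_z(-2 * pi * ft * d)
      s0 <- c(0, 0, 0)
      if (relax_gaps) {
        e2 <- exp(-d / tissue$T2_s); e1 <- exp(-d / tissue$T1_s)
        S <- diag(c(e2, e2, e1)) %*% S
        s0 <- c(0, 0, tissue$M0 * (1 - e1))
      }
    } else {
      beff <- c(a * cos(ph), a * sin(ph), ft - fc)
      nb <- sqrt(sum(beff^2))
      R <- if (nb > 0) rot_axis(beff / nb, -2 * pi * nb * d) else diag(3)
      S <- rot_z(-2 * pi * fc * (t0 + d)) %*% R %*% rot_z(2 * pi * fc * t0)
      s0 <- c(0, 0, 0)
    }
    A <- S %*% A
    b <- S %*% b + s0
    t0 <- t0 + d
  }
  list(A = A, b = as.numeric(b))
}

#' Propagate magnetization through an RF waveform
#'
#' @param m magnetization vector `c(mx, my, mz)` in units of M0.
#' @inheritParams pulse_propagator
#' @return The magnetization after the pulse (length-3 numeric).
#' @examples
#' propagate_pulse(c(0, 0, 1), make_hard_pulse(90, 1e-3),
#'                 tissue_params(Inf, Inf))  # ~ (0, 1, 0)
#' @export
propagate_pulse <- function(m, w, tissue, relax_gaps = TRUE) {
  stopifnot(length(m) == 3, all(is.finite(m)))
  p <- pulse_propagator(w, tissue, relax_gaps)
  as.numeric(p$A %*% m + p$b)
}

#' Free relaxation of magnetization
#'
#' Transverse components decay with T2, the longitudinal component recovers
#' toward M0 with T1. Precession is not included (see [propagate_pulse()] for
#' precessing gaps).
#'
#' @param m magnetization vector `c(mx, my, mz)`.
#' @param t_s relaxation interval (seconds), `>= 0`.
#' @param tissue a [tissue_params].
#' @return relaxed magnetization (length-3 numeric).
#' @export
relax <- function(m, t_s, tissue) {
  if (!is.finite(t_s) && !identical(t_s, Inf)) stop("t_s must be >= 0")
  if (t_s < 0) stop("t_s must be >= 0")
  e2 <- exp(-t_s / tissue$T2_s)
  e1 <- exp(-t_s / tissue$T1_s)
  c(m[1] * e2, m[2] * e2, tissue$M0 + (m[3] - tissue$M0) * e1)
}

#' Simulate a segmented spoiled-GRE excitation train
#'
#' Starting from `start_state` (default thermal equilibrium), an optional
#' saturation prepulse is applied once (followed by perfect spoiling of the
#' transverse components), then per repetition: the excitation waveform is
#' applied, the complex transverse magnetization is recorded, the transverse
#' components are set to zero (perfect spoiling) and the magnetization
#' relaxes for the remainder of the TR.
#'
#' @param w excitation [rf_waveform].
#' @param tissue a [tissue_params].
#' @param tr_s repetition time (seconds); must be `>=` the waveform duration.
#' @param n_excitations number of excitations (e.g. 24 per cardiac segment).
#' @param prepulse optional [rf_waveform] applied once before the train
#'   (e.g. a CHESS fat-saturation pulse), followed by spoiling.
#' @param start_state starting magnetization; default `c(0, 0, M0)`.
#' @param details if `TRUE`, return a data frame with columns
#'   `excitation_index`, `mx`, `my`, `mz`, `mxy` instead of a complex vector.
#' @return Complex vector of length `n_excitations` (Mxy recorded immediately
#'   after each excitation), or a data frame when `details = TRUE`.
#' @examples
#' blood <- tissue_params(1.932, 0.275, f_hz = 0)
#' sig <- simulate_train(make_hard_pulse(18, 0.3e-3), blood,
#'                       tr_s = 5.1e-3, n_excitations = 24)
#' @export
simulate_train <- function(w, tissue, tr_s = 5.1e-3, n_excitations = 24,
                           prepulse = NULL, start_state = NULL,
                           details = FALSE) {
  stopifnot(inherits(w, "rf_waveform"), inherits(tissue, "tissue_params"))
  if (n_excitations < 1) stop("n_excitations must be >= 1")
  if (tr_s < w$total_duration_s)
    stop("invalid timing: TR shorter than the excitation waveform")
  m <- if (is.null(start_state)) c(0, 0, tissue$M0) else as.numeric(start_state)
  if (!is.null(prepulse)) {
    m <- propagate_pulse(m, prepulse, tissue)
    m[1:2] <- 0  # spoiler after the prepulse
  }
  p <- pulse_propagator(w, tissue)
  t_rem <- tr_s - w$total_duration_s
  e2 <- exp(-t_rem / tissue$T2_s)
  e1 <- exp(-t_rem / tissue$T1_s)
  out <- complex(length.out = n_excitations)
  mzs <- numeric(n_excitations)
  for (k in seq_len(n_excitations)) {
    m <- as.numeric(p$A %*% m + p$b)
    out[k] <- complex(real = m[1], imaginary = m[2])
    mzs[k] <- m[3]
    m <- c(0, 0, tissue$M0 + (m[3] - tissue$M0) * e1)
  }
  if (details)
    data.frame(excitation_index = seq_len(n_excitations),
               mx = Re(out), my = Im(out), mz = mzs, mxy = Mod(out))
  else out
}

#' Write a signal trace to CSV
#'
#' @param trace result of [simulate_train()] (complex vector or details
#'   data frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
trace_write_csv <- function(trace, path) {
  if (is.complex(trace))
    trace <- data.frame(excitation_index = seq_along(trace),
                        mx = Re(trace), my = Im(trace), mz = NA_real_,
                        mxy = Mod(trace))
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
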