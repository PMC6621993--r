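# Independent oracles used across the suite.

# --- quaternion rotation oracle -------------------------------------------
# Composes waveform segments as unit quaternions (axis-angle), entirely
# independent of the package's rotation-matrix propagator.

q_axis_angle <- function(u, theta) {
  c(cos(theta / 2), sin(theta / 2) * u)
}

q_mul <- function(a, b) {
  c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(
      a[3] * b[4] - a[4] * b[3],
      a[4] * b[2] - a[2] * b[4],
      a[2] * b[3] - a[3] * b[2]))
}

q_rotate <- function(q, v) {
  p <- q_mul(q_mul(q, c(0, v)), c(q[1], -q[2:4]))
  p[2:4]
}

# quaternion propagation of a relaxation-free waveform for a tissue at f_hz
quat_propagate <- function(m, w, f_hz) {
  q <- c(1, 0, 0, 0)
  t0 <- 0
  s <- w$segments
  ez <- c(0, 0, 1)
  for (i in seq_len(nrow(s))) {
    a <- s$amplitude_hz[i]; fc <- s$carrier_offset_hz[i]
    ph <- s$phase_rad[i]; d <- s$duration_s[i]
    if (a == 0) {
      qi <- q_axis_angle(ez, -2 * pi * f_hz * d)
    } else {
      b <- c(a * cos(ph), a * sin(ph), f_hz - fc)
      nb <- sqrt(sum(b^2))
      qi <- q_mul(q_axis_angle(ez, -2 * pi * fc * (t0 + d)),
                  q_mul(q_axis_angle(b / nb, -2 * pi * nb * d),
                        q_axis_angle(ez, 2 * pi * fc * t0)))
    }
    q <- q_mul(qi, q)
    t0 <- t0 + d
  }
  q_rotate(q, m)
}

# random relaxation-free waveform for oracle comparisons
random_waveform <- function() {
  n <- sample(1:4, 1)
  amp <- stats::runif(n, 0, 600)
  amp[stats::runif(n) < 0.2] <- 0  # occasional gap segments
  rf_waveform(amplitude_hz = amp,
              phase_rad = stats::runif(n, 0, 2 * pi),
              carrier_offset_hz = stats::runif(n, -800, 800),
              duration_s = stats::runif(n, 1e-4, 3e-3))
}

# --- scalar spoiled-GRE recurrence oracle ---------------------------------
# On-resonance hard-pulse train with perfect spoiling: closed-form scalar
# recurrence for Mz with relaxation over the TR remainder.
gre_recurrence <- function(alpha_deg, tr_s, dur_s, n, T1_s, M0 = 1) {
  al <- alpha_deg * pi / 180
  e1 <- exp(-(tr_s - dur_s) / T1_s)
  mz <- M0
  sig <- numeric(n)
  for (k in seq_len(n)) {
    sig[k] <- mz * sin(al)
    mz <- (mz * cos(al)) * e1 + M0 * (1 - e1)
  }
  sig
}

# center of mass of a 1D profile (index units)
profile_com <- function(p) sum(seq_along(p) * p) / sum(p)

# 20-80% edge width of a monotone edge sampled at positions x (oracle for
# the Gaussian-blur closed form), measured on the rising edge
edge_width_2080 <- function(x, y) {
  y <- (y - min(y)) / (max(y) - min(y))
  x20 <- stats::approx(y, x, 0.2, ties = "ordered")$y
  x80 <- stats::approx(y, x, 0.8, ties = "ordered")$y
  abs(x80 - x20)
}
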