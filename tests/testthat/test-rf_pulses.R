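test_that("optimal f_RF solver reproduces known optima and closed form", {
  # printed optima of the fat-nulling condition (10-deg curve)
  expect_equal(round(solve_optimal_frf(1.1e-3, 10, -440)), 469)
  expect_equal(round(solve_optimal_frf(1.1e-3, 10, -480)), 429)
  # alpha = 0 reduces to f_RF = f_fat + 1/tau
  expect_equal(solve_optimal_frf(1.0e-3, 0, -500), 500)
  # frozen independent hand-evaluation of the closed form
  expect_equal(solve_optimal_frf(0.8e-3, 30, -440), 805.65216074,
               tolerance = 1e-10)
})

test_that("optimal tau solver inverts the frequency solver", {
  expect_equal(solve_optimal_tau(469, 18, -440), 1.0987e-3, tolerance = 1e-3)
  expect_equal(solve_optimal_tau(500, 0, -500), 1.0e-3)
  set.seed(42)
  for (i in 1:100) {
    tau <- stats::runif(1, 2e-4, 3e-3)
    al <- stats::runif(1, 0, 120)
    ff <- stats::runif(1, -600, -300)
    frf <- solve_optimal_frf(tau, al, ff)
    expect_equal(solve_optimal_tau(frf, al, ff), tau, tolerance = 1e-9)
  }
})

test_that("optimal f_RF decreases as the fat resonance moves further off", {
  f <- vapply(c(-400, -440, -480), function(ff)
    solve_optimal_frf(1.1e-3, 18, ff), numeric(1))
  expect_true(all(diff(f) < 0))
})

test_that("solvers reject out-of-domain inputs", {
  expect_error(solve_optimal_frf(-1e-3, 18, -440), "tau_s")
  expect_error(solve_optimal_frf(1e-3, 360, -440), "alpha")
  expect_error(solve_optimal_tau(-500, 18, -440), "f_rf_hz")
})

test_that("LIBRE waveform has the documented structure", {
  w <- make_libre(18, 480, 1.1e-3)
  expect_s3_class(w, "rf_waveform")
  expect_equal(nrow(w$segments), 2)
  expect_equal(w$total_duration_s, 2.2e-3, tolerance = 1e-12)
  expect_equal(w$total_duration_s, sum(w$segments$duration_s),
               tolerance = 1e-12)
  expect_equal(w$segments$carrier_offset_hz, c(480, 480))
  expect_equal(w$segments$phase_rad, c(0, pi))
  # nominal angle spread over both sub-pulses
  expect_equal(sum(w$segments$amplitude_hz * w$segments$duration_s) * 360, 18)
  expect_true(all(make_libre(0, 480, 1.1e-3)$segments$amplitude_hz == 0))
})

test_that("LIBRE phase convention nulls fat at the analytic optimum", {
  fat <- tissue_params(Inf, Inf, f_hz = -440)
  frf <- solve_optimal_frf(1.1e-3, 18, -440)
  w <- make_libre(18, frf, 1.1e-3)
  m <- propagate_pulse(c(0, 0, 1), w, fat)
  expect_lt(sqrt(sum(m[1:2]^2)), 0.01)
})

test_that("water-excitation waveform times the fat 180-degree evolution", {
  w <- make_we_11(18, 0.5e-3, 1.1e-3)
  expect_equal(nrow(w$segments), 3)
  expect_equal(w$segments$duration_s, c(0.5e-3, 0.6e-3, 0.5e-3))
  expect_equal(w$total_duration_s, 1.6e-3, tolerance = 1e-12)
  expect_true(all(w$segments$carrier_offset_hz == 0))
  expect_true(all(make_we_11(0)$segments$amplitude_hz == 0))
  expect_error(make_we_11(18, 0.5e-3, 0.4e-3), "invalid timing")
  # exact 180-degree inter-pulse evolution cancels the fat excitation
  fat <- tissue_params(Inf, Inf, f_hz = -440)
  m <- propagate_pulse(c(0, 0, 1), make_we_11(2, 0.5e-3, 1 / (2 * 440)), fat)
  expect_lt(sqrt(sum(m[1:2]^2)), 1e-6)
})

test_that("CHESS pulse is a symmetric Gaussian with the nominal rotation", {
  w <- make_fs_chess(110, 5.12e-3, -407)
  expect_equal(w$total_duration_s, 5.12e-3, tolerance = 1e-12)
  expect_gte(nrow(w$segments), 64)
  a <- w$segments$amplitude_hz
  expect_equal(a, rev(a))  # symmetric envelope
  expect_true(all(w$segments$carrier_offset_hz == -407))
  # on-(carrier)-resonance rotation equals the nominal angle
  iso <- tissue_params(Inf, Inf, f_hz = -407)
  m <- propagate_pulse(c(0, 0, 1), w, iso)
  expect_equal(m[3], cos(110 * pi / 180), tolerance = 0.02)
})

test_that("hard pulse amplitude and rotation follow the nominal angle", {
  w <- make_hard_pulse(18, 0.3e-3)
  expect_equal(w$segments$amplitude_hz, 18 / 360 / 0.3e-3)
  expect_equal(make_hard_pulse(0, 1e-3)$segments$amplitude_hz, 0)
  m <- propagate_pulse(c(0, 0, 1), make_hard_pulse(90, 1e-3),
                       tissue_params(Inf, Inf))
  expect_equal(sqrt(sum(m[1:2]^2)), 1, tolerance = 1e-12)
})

test_that("doubling the nominal angle doubles every amplitude", {
  gens <- list(function(a) make_libre(a, 479, 1.1e-3),
               function(a) make_we_11(a, 0.5e-3, 1.1e-3),
               function(a) make_fs_chess(a, 5.12e-3, -407),
               function(a) make_hard_pulse(a, 0.3e-3))
  for (g in gens)
    expect_equal(g(36)$segments$amplitude_hz,
                 2 * g(18)$segments$amplitude_hz)
})

test_that("waveform invariants are enforced", {
  expect_error(rf_waveform(1, 0, 0, -1e-3), "duration")
  expect_error(rf_waveform(-5, 0, 0, 1e-3), "amplitude")
  expect_error(rf_waveform(1, 0, 0, 1e-3, nominal_angle_deg = 0),
               "zero nominal angle")
})

test_that("waveforms round-trip through CSV and JSON", {
  w <- make_libre(18, 479, 1.1e-3)
  fc <- tempfile(fileext = ".csv")
  fj <- tempfile(fileext = ".json")
  waveform_write_csv(w, fc)
  waveform_write_json(w, fj)
  expect_equal(waveform_read_csv(fc)$segments, w$segments)
  expect_equal(waveform_read_json(fj)$segments, w$segments)
})
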