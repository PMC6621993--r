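# a minimal on-grid "trajectory" along the coordinate axes, used to compare
# the direct DFT summation against an FFT oracle
axis_trajectory <- function(N, voxel_mm = 1) {
  tr <- phyllotaxis_trajectory(3, 1, si_first = FALSE,
                               samples_per_readout = N,
                               k_max_cyc_mm = 1 / (2 * voxel_mm))
  tr$directions <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  tr
}

box_phantom <- function(N, zfrac = 0.4, voxel_mm = 1) {
  labels <- array(0L, dim = c(N, N, N))
  zr <- round(N / 2 + c(-1, 1) * zfrac * N / 2)
  labels[(N / 4):(3 * N / 4), (N / 4):(3 * N / 4), zr[1]:zr[2]] <- 1L
  structure(list(labels = labels,
                 tissue_table = list(t = list(T1_s = 1, T2_s = 0.1, M0 = 1,
                                              chemical_shift_hz = 0)),
                 b0_hz = array(0, dim = c(N, N, N)),
                 voxel_mm = voxel_mm, fov_mm = N * voxel_mm,
                 geometry = list(), b0_model = "none"),
            class = "phantom_volume")
}

test_that("phyllotaxis trajectory produces unit-norm interleaved lines", {
  tr <- phyllotaxis_trajectory(500, 24, si_first = TRUE)
  expect_equal(nrow(tr$directions), 12000)
  expect_lt(max(abs(1 - sqrt(rowSums(tr$directions^2)))), 1e-12)
  first_of_segment <- tr$directions[seq(1, 12000, by = 24), , drop = FALSE]
  expect_true(all(first_of_segment[, 3] == 1))
  expect_true(all(abs(first_of_segment[, 1:2]) == 0))
})

test_that("2000 phyllotaxis lines cover the hemisphere without large gaps", {
  tr <- phyllotaxis_trajectory(2000, 1, si_first = FALSE)
  D <- tr$directions
  set.seed(5)
  z <- abs(stats::rnorm(10000)); xy <- matrix(stats::rnorm(20000), ncol = 2)
  Q <- cbind(xy, z)
  Q <- Q / sqrt(rowSums(Q^2))
  worst <- 0
  for (i0 in seq(1, nrow(Q), by = 1000)) {
    block <- Q[i0:(i0 + 999), ]
    # readouts are diameters: use |dot|
    gaps <- acos(pmin(1, apply(abs(block %*% t(D)), 1, max)))
    worst <- max(worst, max(gaps))
  }
  expect_lt(worst * 180 / pi, 12)
})

test_that("the DC sample equals the phantom volume integral", {
  ph <- box_phantom(16)
  tr <- phyllotaxis_trajectory(4, 6, samples_per_readout = 16,
                               k_max_cyc_mm = 0.5)
  ks <- synthesize_kspace(ph, tr)
  K <- trajectory_sample_points(tr)
  dc <- which(rowSums(K^2) == 0)
  expect_true(length(dc) >= 1)
  expect_equal(unique(round(Mod(ks$samples[dc]), 6)), sum(ph$labels == 1))
})

test_that("a single bright voxel gives a pure phase ramp", {
  N <- 16
  labels <- array(0L, dim = c(N, N, N))
  labels[11, 6, 9] <- 1L
  ph <- box_phantom(N)
  ph$labels <- labels
  tr <- phyllotaxis_trajectory(3, 5, samples_per_readout = 16,
                               k_max_cyc_mm = 0.5)
  ks <- synthesize_kspace(ph, tr)
  expect_equal(Mod(ks$samples), rep(1, length(ks$samples)), tolerance = 1e-9)
  K <- trajectory_sample_points(tr)
  r0 <- (c(11, 6, 9) - 1 - N / 2) * ph$voxel_mm
  want <- (-2 * pi * as.numeric(K %*% r0)) %% (2 * pi)
  got <- Arg(ks$samples) %% (2 * pi)
  dphi <- (got - want + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi)), 1e-6)
})

test_that("on-grid synthesized k-space matches the FFT oracle", {
  N <- 32
  ph <- make_cylinder_phantom(N, voxel_mm = 1)
  tr <- axis_trajectory(N)
  ks <- synthesize_kspace(ph, tr)
  sm <- phantom_signal_map(ph, NULL)
  # oracle: centered DFT of the signal map along each axis line
  shift <- function(v) c(v[(N / 2 + 1):N], v[1:(N / 2)])
  F <- stats::fft(sm)
  lines <- list(F[, 1, 1], F[1, , 1], F[1, 1, ])  # kx, ky, kz axis lines
  ph_fix <- (-1)^(0:(N - 1))  # voxel-centering phase for centered coords
  for (li in 1:3) {
    got <- ks$samples[((li - 1) * N + 1):(li * N)]
    want <- shift(lines[[li]]) * ph_fix  # modulation from the N/2 origin shift
    expect_lt(max(Mod(got - want)) / max(Mod(want)), 1e-6)
  }
})

test_that("noise injection is seed-deterministic and sized correctly", {
  ph <- box_phantom(16)
  tr <- phyllotaxis_trajectory(2, 4, samples_per_readout = 16,
                               k_max_cyc_mm = 0.5)
  a <- synthesize_kspace(ph, tr, noise_sigma = 3, seed = 99)
  b <- synthesize_kspace(ph, tr, noise_sigma = 3, seed = 99)
  c0 <- synthesize_kspace(ph, tr)
  expect_identical(a$samples, b$samples)
  expect_equal(stats::sd(Re(a$samples - c0$samples)), 3, tolerance = 0.3)
})

test_that("gridding PSF is centered and the adjoint pairing holds", {
  tr <- phyllotaxis_trajectory(40, 8, si_first = FALSE,
                               samples_per_readout = 32, k_max_cyc_mm = 0.5)
  ks <- structure(list(samples = rep(1 + 0i, 320 * 32), noise_sigma = 0,
                       seed = NULL), class = "kspace_data")
  psf <- grid_reconstruct(ks, tr, 16)
  ctr <- which(psf$data == max(psf$data), arr.ind = TRUE)
  expect_equal(as.numeric(ctr), rep(9, 3))  # N/2 + 1 for N = 16
  # adjointness of spread/interp on a random small instance
  set.seed(21)
  G <- 12; W <- 4; beta <- librepulse:::kb_beta(W, 2)
  coords <- cbind(stats::runif(50, 2, G - 3), stats::runif(50, 2, G - 3),
                  stats::runif(50, 2, G - 3))
  v <- complex(real = stats::rnorm(50), imaginary = stats::rnorm(50))
  x <- array(complex(real = stats::rnorm(G^3),
                     imaginary = stats::rnorm(G^3)), dim = c(G, G, G))
  lhs <- sum(Conj(librepulse:::kb_spread(v, coords, G, W, beta)) * x)
  rhs <- sum(Conj(v) * librepulse:::kb_interp(x, coords, W, beta))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-3)
})

test_that("complex reconstruction is linear in the k-space data", {
  tr <- phyllotaxis_trajectory(10, 6, si_first = FALSE,
                               samples_per_readout = 16, k_max_cyc_mm = 0.5)
  n <- 60 * 16
  set.seed(31)
  k1 <- structure(list(samples = complex(real = stats::rnorm(n),
                                         imaginary = stats::rnorm(n)),
                       noise_sigma = 0, seed = NULL), class = "kspace_data")
  k2 <- structure(list(samples = complex(real = stats::rnorm(n),
                                         imaginary = stats::rnorm(n)),
                       noise_sigma = 0, seed = NULL), class = "kspace_data")
  kc <- structure(list(samples = 2.5 * k1$samples + k2$samples,
                       noise_sigma = 0, seed = NULL), class = "kspace_data")
  r1 <- grid_reconstruct(k1, tr, 16, magnitude = FALSE)$data
  r2 <- grid_reconstruct(k2, tr, 16, magnitude = FALSE)$data
  rc <- grid_reconstruct(kc, tr, 16, magnitude = FALSE)$data
  expect_lt(max(Mod(rc - (2.5 * r1 + r2))) / max(Mod(rc)), 1e-9)
})

test_that("20%-Nyquist reconstruction recovers the phantom signal map", {
  ph <- make_cylinder_phantom(32, voxel_mm = 220 / 32)
  sm <- phantom_signal_map(ph, NULL)
  tr <- phyllotaxis_trajectory(14, 24, si_first = FALSE,
                               samples_per_readout = 64,
                               k_max_cyc_mm = 1 / (2 * ph$voxel_mm))
  ks <- synthesize_kspace(ph, tr)
  img <- grid_reconstruct(ks, tr, 32)
  sc <- sum(img$data * sm) / sum(img$data^2)
  nrmse <- sqrt(mean((sc * img$data - sm)^2)) / diff(range(sm))
  expect_lt(nrmse, 0.15)
})

test_that("SI projection is supported on the object and tracks z shifts", {
  N <- 32
  ph <- box_phantom(N, zfrac = 0.4)
  tr <- phyllotaxis_trajectory(3, 8, si_first = TRUE,
                               samples_per_readout = N, k_max_cyc_mm = 0.5)
  ks <- synthesize_kspace(ph, tr)
  prof <- si_projection(ks, tr, segment_index = 2)
  expect_length(prof, N)
  zmask <- abs((seq_len(N) - 1 - N / 2)) <= 0.4 * N / 2 + 1
  expect_lt(max(prof[!zmask]), 0.1 * max(prof))
  # whole-object shift moves the projection's center of mass
  dz <- 4
  ph2 <- ph
  ph2$labels <- array(0L, dim = dim(ph$labels))
  ph2$labels[, , (1 + dz):N] <- ph$labels[, , 1:(N - dz)]
  ks2 <- synthesize_kspace(ph2, tr)
  prof2 <- si_projection(ks2, tr, segment_index = 2)
  expect_equal(profile_com(prof2) - profile_com(prof), dz, tolerance = 1)
  # zero k-space gives a zero profile, non-SI trajectories are rejected
  ks0 <- ks; ks0$samples <- ks$samples * 0
  expect_equal(si_projection(ks0, tr, 1), rep(0, N))
  tr_nosi <- phyllotaxis_trajectory(3, 8, si_first = FALSE,
                                    samples_per_readout = N,
                                    k_max_cyc_mm = 0.5)
  expect_error(si_projection(ks, tr_nosi, 1), "unsupported trajectory")
})

test_that("trajectory and k-space round-trip through CSV", {
  tr <- phyllotaxis_trajectory(3, 4, samples_per_readout = 8,
                               k_max_cyc_mm = 0.5)
  f <- tempfile(fileext = ".csv")
  trajectory_write_csv(tr, f)
  d <- utils::read.csv(f)
  expect_equal(nrow(d), 12)
  expect_equal(as.matrix(d[, c("dx", "dy", "dz")]), tr$directions,
               ignore_attr = TRUE)
  ph <- box_phantom(16)
  tr2 <- phyllotaxis_trajectory(2, 4, samples_per_readout = 16,
                                k_max_cyc_mm = 0.5)
  ks <- synthesize_kspace(ph, tr2)
  f2 <- tempfile(fileext = ".csv")
  kspace_write_csv(ks, tr2, f2)
  expect_equal(kspace_read_csv(f2)$samples, ks$samples, tolerance = 1e-12)
})
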