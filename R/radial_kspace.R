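#' Segmented 3D spiral phyllotaxis radial trajectory
#'
#' Readout directions are arranged on the hemisphere following the spiral
#' phyllotaxis pattern: global line index `n` (0-based, `N` lines total)
#' receives polar angle `theta = (pi/2) * sqrt(n / N)` and azimuth
#' `phi = n * 137.51` degrees (golden angle). Lines are interleaved across
#' segments so that segment `l` collects lines `n = j * n_segments + l`
#' (`j = 0 .. lines_per_segment - 1`), making each segment itself a smooth
#' spiral from the pole toward the equator, rotated by the golden angle
#' against its neighbours. With `si_first`, the first line of every segment
#' is replaced by the superior-inferior direction (0, 0, 1), from which
#' respiratory self-navigation projections are obtained.
#'
#' @param n_segments number of segments (e.g. one per heartbeat).
#' @param lines_per_segment radial lines per segment (e.g. 24).
#' @param si_first replace the first line of each segment by (0,0,1)?
#' @param samples_per_readout samples along each readout (diameter spokes,
#'   2x oversampled readout by convention).
#' @param k_max_cyc_mm maximum sampled spatial frequency (cycles/mm);
#'   `1 / (2 * voxel)` for a target voxel size.
#' @return Object of class `radial_trajectory`: list with `directions`
#'   (N x 3 unit vectors in acquisition order), `n_segments`,
#'   `lines_per_segment`, `samples_per_readout`, `k_max_cyc_mm`, `si_first`,
#'   and `variant` metadata.
#' @examples
#' tr <- phyllotaxis_trajectory(10, 24)
#' range(sqrt(rowSums(tr$directions^2)))  # all unit norm
#' @export
phyllotaxis_trajectory <- function(n_segments, lines_per_segment,
                                   si_first = TRUE,
                                   samples_per_readout = 64,
                                   k_max_cyc_mm = 1 / (2 * 1.1)) {
  if (n_segments < 1 || lines_per_segment < 1)
    stop("n_segments and lines_per_segment must be >= 1")
  N <- n_segments * lines_per_segment
  golden <- 137.51 * pi / 180
  # acquisition order: segment-major; line j of segment l is global index n
  l <- rep(seq_len(n_segments) - 1, each = lines_per_segment)
  j <- rep(seq_len(lines_per_segment) - 1, times = n_segments)
  n <- j * n_segments + l
  theta <- (pi / 2) * sqrt(n / N)
  phi <- n * golden
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  if (si_first) dirs[j == 0, ] <- rep(c(0, 0, 1), each = sum(j == 0))
  structure(
    list(directions = dirs, n_segments = n_segments,
         lines_per_segment = lines_per_segment,
         samples_per_readout = samples_per_readout,
         k_max_cyc_mm = k_max_cyc_mm, si_first = si_first,
         variant = "hemisphere sqrt polar law, golden-angle azimuth 137.51 deg"),
    class = "radial_trajectory")
}

#' @export
print.radial_trajectory <- function(x, ...) {
  cat(sprintf("<radial_trajectory> %d segments x %d lines, %d samples/readout, k_max %.4g /mm%s\n",
              x$n_segments, x$lines_per_segment, x$samples_per_readout,
              x$k_max_cyc_mm, if (x$si_first) ", SI-first" else ""))
  invisible(x)
}

#' Sample locations of a radial trajectory
#'
#' Each readout spans the diameter from `-k_max` to `+k_max - dk` in
#' `samples_per_readout` steps (FFT-compatible convention).
#'
#' @param traj a `radial_trajectory`.
#' @return matrix (total lines * samples_per_readout) x 3 of k-space
#'   locations (cycles/mm), sample-major within each line.
#' @export
trajectory_sample_points <- function(traj) {
  S <- traj$samples_per_readout
  radii <- (seq_len(S) - 1 - S / 2) * (2 * traj$k_max_cyc_mm / S)
  nlines <- nrow(traj$directions)
  # line-major ordering: all samples of line 1, then line 2, ...
  d <- traj$directions[rep(seq_len(nlines), each = S), , drop = FALSE]
  d * rep(radii, times = nlines)
}

#' Write a trajectory as CSV
#'
#' Columns: `segment`, `line`, `dx`, `dy`, `dz` (unit readout directions).
#'
#' @param traj a `radial_trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
trajectory_write_csv <- function(traj, path) {
  d <- traj$directions
  out <- data.frame(
    segment = rep(seq_len(traj$n_segments), each = traj$lines_per_segment),
    line = rep(seq_len(traj$lines_per_segment), times = traj$n_segments),
    dx = d[, 1], dy = d[, 2], dz = d[, 3])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Synthesize radial k-space from a digital phantom
#'
#' The per-voxel signal amplitude is obtained from the Bloch simulation of
#' the acquisition's excitation train (see [phantom_signal_map()]), and each
#' k-space sample is the discrete Fourier sum
#' `sum_v s(v) * exp(-2i * pi * k . r_v)` over non-zero voxels, evaluated by
#' direct summation. Optional complex white Gaussian noise is added per
#' sample.
#'
#' @param phantom a `phantom_volume` (see [make_cylinder_phantom()]).
#' @param traj a `radial_trajectory`.
#' @param protocol acquisition settings passed to [phantom_signal_map()]
#'   (list with `method`, `method_args`, `tr_s`, `n_excitations`,
#'   `aggregate`), or `NULL` to use label M0 as signal directly.
#' @param noise_sigma standard deviation of complex Gaussian noise per
#'   sample (same scale as the signal sum); 0 disables noise.
#' @param seed RNG seed used when noise is added (recorded in the output).
#' @param signal_map optional precomputed voxel signal array overriding
#'   `protocol`.
#' @return Object of class `kspace_data`: list with `samples` (complex
#'   vector aligned to [trajectory_sample_points()]), `noise_sigma`, `seed`.
#' @export
synthesize_kspace <- function(phantom, traj, protocol = NULL,
                              noise_sigma = 0, seed = NULL,
                              signal_map = NULL) {
  stopifnot(inherits(phantom, "phantom_volume"),
            inherits(traj, "radial_trajectory"))
  if (is.null(signal_map))
    signal_map <- phantom_signal_map(phantom, protocol)
  nz <- which(signal_map != 0)
  if (length(nz) == 0) stop("empty phantom: no non-zero signal voxels")
  dims <- dim(signal_map)
  idx <- arrayInd(nz, dims)
  # voxel-centered coordinates (mm), origin at the volume center
  r <- (idx - 1 - rep(dims / 2, each = nrow(idx))) * phantom$voxel_mm
  s <- signal_map[nz]
  K <- trajectory_sample_points(traj)
  samples <- direct_dft_sum(K, r, s)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(samples)
    samples <- samples + complex(real = stats::rnorm(n, 0, noise_sigma),
                                 imaginary = stats::rnorm(n, 0, noise_sigma))
  }
  structure(list(samples = samples, noise_sigma = noise_sigma, seed = seed),
            class = "kspace_data")
}

# chunked direct summation of sum_v s_v exp(-2i pi K.r_v)
direct_dft_sum <- function(K, r, s, chunk = 2048L) {
  M <- nrow(K)
  out <- complex(length.out = M)
  for (i0 in seq(1L, M, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, M)
    ph <- K[i0:i1, , drop = FALSE] %*% t(r)  # (m x V)
    out[i0:i1] <- exp(-2i * pi * ph) %*% s
  }
  out
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %d samples, noise sigma %.4g\n",
              length(x$samples), x$noise_sigma))
  invisible(x)
}

#' Write / read k-space samples as CSV
#'
#' Columns: `kx`, `ky`, `kz` (cycles/mm), `re`, `im`.
#'
#' @param k a `kspace_data`.
#' @param traj the matching `radial_trajectory`.
#' @param path file path.
#' @return `path` invisibly (writer); a `kspace_data` (reader).
#' @export
kspace_write_csv <- function(k, traj, path) {
  K <- trajectory_sample_points(traj)
  out <- data.frame(kx = K[, 1], ky = K[, 2], kz = K[, 3],
                    re = Re(k$samples), im = Im(k$samples))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname kspace_write_csv
#' @export
kspace_read_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(samples = complex(real = d$re, imaginary = d$im),
                 noise_sigma = NA_real_, seed = NULL),
            class = "kspace_data")
}

# Kaiser-Bessel kernel (width W in oversampled grid units) and its transform
kb_beta <- function(W, osf) pi * sqrt((W / osf)^2 * (osf - 0.5)^2 - 0.8)

kb_kernel <- function(u, W, beta) {
  x <- 1 - (2 * u / W)^2
  out <- numeric(length(u))
  ok <- x > 0
  out[ok] <- besselI(beta * sqrt(x[ok]), 0) / besselI(beta, 0)
  out
}

# Fourier transform of the KB kernel at image position x (pixels of the
# oversampled image of size G)
kb_apod <- function(x, G, W, beta) {
  arg2 <- (pi * W * x / G)^2 - beta^2
  out <- numeric(length(x))
  pos <- arg2 > 0
  sp <- sqrt(arg2[pos])
  out[pos] <- sin(sp) / sp
  sn <- sqrt(-arg2[!pos])
  out[!pos] <- ifelse(sn == 0, 1, sinh(sn) / sn)
  out / (sinh(beta) / beta)  # normalize to 1 at center
}

# scatter (adjoint) gridding: samples at fractional grid coords -> G^3 array
kb_spread <- function(vals, gcoord, G, W, beta) {
  acc_re <- numeric(G^3)
  acc_im <- numeric(G^3)
  base <- floor(gcoord)
  offs <- seq_len(W) - W / 2  # e.g. W=4: -1,0,1,2 relative to floor
  for (ox in offs) for (oy in offs) for (oz in offs) {
    px <- base[, 1] + ox; py <- base[, 2] + oy; pz <- base[, 3] + oz
    wx <- kb_kernel(gcoord[, 1] - px, W, beta)
    wy <- kb_kernel(gcoord[, 2] - py, W, beta)
    wz <- kb_kernel(gcoord[, 3] - pz, W, beta)
    w <- wx * wy * wz
    inb <- px >= 0 & px < G & py >= 0 & py < G & pz >= 0 & pz < G & w > 0
    if (!any(inb)) next
    lin <- 1 + px[inb] + G * (py[inb] + G * pz[inb])
    vr <- rowsum(c(Re(vals[inb]) * w[inb]), lin)
    vi <- rowsum(c(Im(vals[inb]) * w[inb]), lin)
    ii <- as.integer(rownames(vr))
    acc_re[ii] <- acc_re[ii] + vr[, 1]
    acc_im[ii] <- acc_im[ii] + vi[, 1]
  }
  array(complex(real = acc_re, imaginary = acc_im), dim = c(G, G, G))
}

# forward interpolation (transpose of kb_spread) for adjointness checks
kb_interp <- function(grid, gcoord, W, beta) {
  G <- dim(grid)[1]
  out <- complex(length.out = nrow(gcoord))
  base <- floor(gcoord)
  offs <- seq_len(W) - W / 2
  for (ox in offs) for (oy in offs) for (oz in offs) {
    px <- base[, 1] + ox; py <- base[, 2] + oy; pz <- base[, 3] + oz
    wx <- kb_kernel(gcoord[, 1] - px, W, beta)
    wy <- kb_kernel(gcoord[, 2] - py, W, beta)
    wz <- kb_kernel(gcoord[, 3] - pz, W, beta)
    w <- wx * wy * wz
    inb <- px >= 0 & px < G & py >= 0 & py < G & pz >= 0 & pz < G & w > 0
    if (!any(inb)) next
    lin <- 1 + px[inb] + G * (py[inb] + G * pz[inb])
    out[inb] <- out[inb] + grid[lin] * w[inb]
  }
  out
}

fftshift3 <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  x[ix[[1]], ix[[2]], ix[[3]]]
}

ifftshift3 <- function(x) {
  d <- dim(x)
  ix <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)))
  x[ix[[1]], ix[[2]], ix[[3]]]
}

#' Gridding reconstruction of radial k-space
#'
#' Density-compensated adjoint gridding with a Kaiser-Bessel kernel onto an
#' oversampled Cartesian grid, inverse FFT, deapodization and central crop.
#' Density compensation uses the analytic `|k|^2` ramp appropriate for 3D
#' radial sampling, with a one-sample plateau at `k = 0`.
#'
#' @param k a `kspace_data`.
#' @param traj the matching `radial_trajectory`.
#' @param matrix_size reconstructed image matrix (isotropic, `>= 16`).
#' @param oversample grid oversampling factor (default 2).
#' @param kernel_width Kaiser-Bessel kernel width in oversampled grid units
#'   (default 4).
#' @param magnitude return the magnitude image (default); set `FALSE` to get
#'   the complex image (used for linearity checks).
#' @return An `image_volume`: list with `data` (matrix_size^3 array),
#'   `voxel_mm`.
#' @export
grid_reconstruct <- function(k, traj, matrix_size, oversample = 2,
                             kernel_width = 4, magnitude = TRUE) {
  stopifnot(inherits(k, "kspace_data"), inherits(traj, "radial_trajectory"))
  if (matrix_size < 16) stop("matrix_size must be >= 16")
  K <- trajectory_sample_points(traj)
  if (nrow(K) != length(k$samples))
    stop("trajectory/sample mismatch")
  N <- matrix_size
  G <- as.integer(round(oversample * N))
  W <- kernel_width
  beta <- kb_beta(W, oversample)
  voxel_mm <- 1 / (2 * traj$k_max_cyc_mm)
  dk_grid <- 1 / (G * voxel_mm)          # oversampled grid spacing
  # density compensation: |k|^2 ramp, flat one-sample plateau at k = 0;
  # repeated readout directions (e.g. the SI line of every segment) are
  # downweighted by their multiplicity
  kr <- sqrt(rowSums(K^2))
  dk_r <- 2 * traj$k_max_cyc_mm / traj$samples_per_readout
  dens <- pmax(kr, dk_r / 2)^2
  key <- apply(round(traj$directions, 9), 1, paste, collapse = ",")
  mult <- as.numeric(table(key)[key])
  dens <- dens / rep(mult, each = traj$samples_per_readout)
  gcoord <- K / dk_grid + G / 2
  grid <- kb_spread(k$samples * dens, gcoord, G, W, beta)
  img <- fftshift3(stats::fft(ifftshift3(grid), inverse = TRUE)) / length(grid)
  lo <- G / 2 - N / 2 + 1; hi <- G / 2 + N / 2
  img <- img[lo:hi, lo:hi, lo:hi]
  x <- (seq_len(N) - 1 - N / 2)
  ap <- kb_apod(x, G, W, beta)
  deap <- outer(outer(ap, ap), ap)
  img <- img / deap
  structure(list(data = if (magnitude) Mod(img) else img,
                 voxel_mm = voxel_mm),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, voxel %.4g mm\n",
              paste(dim(x$data), collapse = "x"), x$voxel_mm))
  invisible(x)
}

#' Superior-inferior projection from a segment's first readout
#'
#' Fourier transforms the first (superior-inferior oriented) readout of a
#' segment into a 1D projection of the object along z, as used for
#' respiratory self-navigation.
#'
#' @param k a `kspace_data`.
#' @param traj the matching `radial_trajectory` (must have `si_first`).
#' @param segment_index which segment's first readout to transform.
#' @return numeric magnitude profile of length `samples_per_readout`.
#' @export
si_projection <- function(k, traj, segment_index = 1) {
  stopifnot(inherits(k, "kspace_data"), inherits(traj, "radial_trajectory"))
  if (!traj$si_first)
    stop("unsupported trajectory: si_first was not set")
  if (segment_index < 1 || segment_index > traj$n_segments)
    stop("segment_index out of range")
  S <- traj$samples_per_readout
  line0 <- (segment_index - 1) * traj$lines_per_segment  # first line (0-based)
  idx <- line0 * S + seq_len(S)
  readout <- k$samples[idx]
  prof <- stats::fft(c(readout[(S / 2 + 1):S], readout[1:(S / 2)]),
                     inverse = TRUE) / S
  Mod(c(prof[(S / 2 + 1):S], prof[1:(S / 2)]))
}

#' Write / read images as NIfTI
#'
#' @param image an `image_volume`.
#' @param path NIfTI file path (`.nii`).
#' @return `path` invisibly (writer); an `image_volume` (reader).
#' @export
image_write_nifti <- function(image, path) {
  stopifnot(inherits(image, "image_volume"))
  img <- RNifti::asNifti(image$data,
                         pixdim = rep(image$voxel_mm, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname image_write_nifti
#' @export
image_read_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(data = as.array(img),
                 voxel_mm = RNifti::pixdim(img)[1]),
            class = "image_volume")
}
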