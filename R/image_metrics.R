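#' ROI signal-to-noise ratio
#'
#' SNR is the mean magnitude signal inside the signal ROI divided by the
#' sample standard deviation of the magnitude image inside the noise (air)
#' ROI. No Rician magnitude-bias correction is applied.
#'
#' @param image an `image_volume` or numeric array.
#' @param signal_roi,noise_roi logical arrays matching the image dimensions;
#'   the noise ROI must be non-empty and disjoint from the signal ROI.
#' @return SNR (dimensionless).
#' @examples
#' img <- array(c(rep(50, 10), rnorm(90, 0, 5)), dim = c(10, 10, 1))
#' @export
roi_snr <- function(image, signal_roi, noise_roi) {
  a <- image_data(image)
  check_rois(a, signal_roi, noise_roi)
  sdn <- stats::sd(a[noise_roi])
  if (sdn == 0) stop("undefined SNR: noise ROI has zero standard deviation")
  mean(a[signal_roi]) / sdn
}

#' ROI contrast-to-noise ratio
#'
#' `(mean(roi_a) - mean(roi_b)) / sd(noise_roi)`; equals
#' `roi_snr(a) - roi_snr(b)` exactly.
#'
#' @param image an `image_volume` or numeric array.
#' @param roi_a,roi_b,noise_roi logical arrays matching the image.
#' @return CNR (dimensionless, signed).
#' @export
roi_cnr <- function(image, roi_a, roi_b, noise_roi) {
  a <- image_data(image)
  check_rois(a, roi_a, noise_roi)
  check_rois(a, roi_b, noise_roi)
  sdn <- stats::sd(a[noise_roi])
  if (sdn == 0) stop("undefined CNR: noise ROI has zero standard deviation")
  (mean(a[roi_a]) - mean(a[roi_b])) / sdn
}

image_data <- function(image) {
  if (inherits(image, "image_volume")) image$data else image
}

check_rois <- function(a, signal_roi, noise_roi) {
  if (!all(dim(signal_roi) == dim(a)) || !all(dim(noise_roi) == dim(a)))
    stop("ROI dimensions must match the image")
  if (!any(signal_roi) || !any(noise_roi))
    stop("ROIs must be non-empty")
  if (any(signal_roi & noise_roi))
    stop("noise ROI must be disjoint from signal ROIs")
  invisible(TRUE)
}

#' Vessel length
#'
#' Arc length of a centerline polyline: the sum of consecutive-point
#' Euclidean distances.
#'
#' @param centerline n x 3 matrix of ordered points (mm), `n >= 2`.
#' @return length in mm.
#' @examples
#' vessel_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
vessel_length <- function(centerline) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  sum(sqrt(rowSums(diff(centerline)^2)))
}

#' Vessel sharpness from perpendicular intensity profiles
#'
#' At regularly spaced points along the proximal `eval_length_mm` of the
#' centerline, the image is sampled along a line perpendicular to the local
#' centerline tangent. For each of the two vessel borders, the distance `d`
#' (mm) between the 20% and 80% levels of the background-subtracted local
#' profile maximum is found by linear interpolation, and the border
#' sharpness is `(voxel_mm / d) * 100`, capped at 100. The returned value is
#' the mean over both borders and all evaluated points. A border without a
#' detectable vessel peak is skipped; if more than half of the points are
#' skipped the measurement fails.
#'
#' @param image an `image_volume` (vessel brighter than background).
#' @param centerline n x 3 matrix of points (mm, voxel centers at
#'   `(i - 0.5) * voxel_mm`).
#' @param eval_length_mm proximal centerline length to evaluate (default
#'   40 mm, i.e. 4 cm).
#' @param point_spacing_mm spacing of evaluation points (default one voxel).
#' @param profile_halfwidth_mm half-width of the sampled profile (defaults
#'   to 4x an estimated vessel radius, at least 6 voxels).
#' @return sharpness in percent (0-100), with attribute `n_points` (used)
#'   and `n_skipped`.
#' @export
vessel_sharpness <- function(image, centerline, eval_length_mm = 40,
                             point_spacing_mm = NULL,
                             profile_halfwidth_mm = NULL) {
  stopifnot(inherits(image, "image_volume"))
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2) stop("centerline needs at least 2 points")
  vx <- image$voxel_mm
  if (is.null(point_spacing_mm)) point_spacing_mm <- vx
  cl <- resample_polyline(centerline, point_spacing_mm)
  arc <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  cl <- cl[arc <= eval_length_mm, , drop = FALSE]
  if (nrow(cl) < 3) stop("centerline shorter than the evaluation length grid")
  # drop endpoints (tangent needs neighbours)
  pts <- 2:(nrow(cl) - 1)
  if (is.null(profile_halfwidth_mm))
    profile_halfwidth_mm <- max(6 * vx, 8)
  step <- 0.25 * vx
  offs <- seq(-profile_halfwidth_mm, profile_halfwidth_mm, by = step)
  vals <- c(); skipped <- 0L
  for (i in pts) {
    tanv <- cl[i + 1, ] - cl[i - 1, ]
    tanv <- tanv / sqrt(sum(tanv^2))
    # a stable perpendicular direction
    e <- c(1, 0, 0)
    if (abs(sum(tanv * e)) > 0.9) e <- c(0, 1, 0)
    u <- e - sum(e * tanv) * tanv
    u <- u / sqrt(sum(u^2))
    P <- matrix(cl[i, ], length(offs), 3, byrow = TRUE) + outer(offs, u)
    prof <- interp3(image$data, P / vx + 0.5)
    res <- profile_edge_sharpness(prof, offs, vx)
    if (is.null(res)) skipped <- skipped + 1L else vals <- c(vals, res)
  }
  if (skipped > length(pts) / 2)
    stop("vessel sharpness failed: no detectable vessel peak at most points")
  out <- mean(vals)
  attr(out, "n_points") <- length(pts) - skipped
  attr(out, "n_skipped") <- skipped
  out
}

# 20-80% edge sharpness (%) of both borders of one profile; NULL if no peak
profile_edge_sharpness <- function(prof, offs, voxel_mm) {
  bg <- min(prof)
  pk <- which.max(prof)
  amp <- prof[pk] - bg
  if (amp <= 0 || !is.finite(amp)) return(NULL)
  # require the peak to sit in the interior and be reasonably central
  if (pk <= 2 || pk >= length(prof) - 1) return(NULL)
  lo20 <- bg + 0.2 * amp
  lo80 <- bg + 0.8 * amp
  edge <- function(side) {
    ix <- if (side == "left") seq(pk, 1) else seq(pk, length(prof))
    p <- prof[ix]; o <- offs[ix]
    c80 <- first_crossing(p, o, lo80, downward = TRUE)
    c20 <- first_crossing(p, o, lo20, downward = TRUE)
    if (is.na(c80) || is.na(c20)) return(NA_real_)
    abs(c20 - c80)
  }
  d <- c(edge("left"), edge("right"))
  d <- d[!is.na(d) & d > 0]
  if (length(d) == 0) return(NULL)
  pmin(100, voxel_mm / d * 100)
}

# first position (linear interpolation) where p drops below level, walking
# outward from the peak
first_crossing <- function(p, o, level, downward = TRUE) {
  below <- p < level
  j <- which(below)[1]
  if (is.na(j) || j == 1) return(NA_real_)
  o[j - 1] + (level - p[j - 1]) / (p[j] - p[j - 1]) * (o[j] - o[j - 1])
}

# trilinear interpolation; pts in voxel index units (1-based centers)
interp3 <- function(vol, pts) {
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1); y0 <- pmin(floor(y), d[2] - 1)
  z0 <- pmin(floor(z), d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  v <- function(ix, iy, iz) vol[cbind(ix, iy, iz)]
  v000 <- v(x0, y0, z0);     v100 <- v(x0 + 1, y0, z0)
  v010 <- v(x0, y0 + 1, z0); v110 <- v(x0 + 1, y0 + 1, z0)
  v001 <- v(x0, y0, z0 + 1); v101 <- v(x0 + 1, y0, z0 + 1)
  v011 <- v(x0, y0 + 1, z0 + 1); v111 <- v(x0 + 1, y0 + 1, z0 + 1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# resample a polyline to (approximately) uniform spacing
resample_polyline <- function(pl, spacing) {
  seg <- sqrt(rowSums(diff(pl)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[length(arc)]
  s <- seq(0, total, by = spacing)
  out <- sapply(1:3, function(j) stats::approx(arc, pl[, j], xout = s)$y)
  matrix(out, ncol = 3)
}

#' Read / write centerlines as CSV
#'
#' Columns `x_mm`, `y_mm`, `z_mm`.
#'
#' @param centerline n x 3 matrix (mm).
#' @param path file path.
#' @return `path` invisibly (writer); an n x 3 matrix (reader).
#' @export
centerline_write_csv <- function(centerline, path) {
  cl <- as.matrix(centerline)
  utils::write.csv(data.frame(x_mm = cl[, 1], y_mm = cl[, 2], z_mm = cl[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname centerline_write_csv
#' @export
centerline_read_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x_mm", "y_mm", "z_mm")])
}

#' Compile an image-quality metric report
#'
#' @param image an `image_volume`.
#' @param rois named list of logical ROI arrays; must contain `noise`, plus
#'   any signal ROIs.
#' @param centerline optional centerline (mm) for vessel metrics.
#' @param cnr_pairs optional list of 2-element character vectors naming ROI
#'   pairs for CNR.
#' @return list with `snr` (named), `cnr` (named), `vessel_sharpness_pct`,
#'   `vessel_length_mm` and `metadata` (notes the absence of a Rician bias
#'   correction).
#' @export
metric_report <- function(image, rois, centerline = NULL,
                          cnr_pairs = NULL) {
  stopifnot("noise" %in% names(rois))
  signal_names <- setdiff(names(rois), "noise")
  snr <- vapply(signal_names, function(nm)
    roi_snr(image, rois[[nm]], rois$noise), numeric(1))
  cnr <- NULL
  if (!is.null(cnr_pairs)) {
    cnr <- vapply(cnr_pairs, function(p)
      roi_cnr(image, rois[[p[1]]], rois[[p[2]]], rois$noise), numeric(1))
    names(cnr) <- vapply(cnr_pairs, paste, character(1), collapse = "_vs_")
  }
  out <- list(snr = as.list(snr), cnr = as.list(cnr),
              metadata = list(noise_sd_rician_corrected = FALSE))
  if (!is.null(centerline)) {
    out$vessel_sharpness_pct <- as.numeric(vessel_sharpness(image, centerline))
    out$vessel_length_mm <- vessel_length(centerline)
  }
  out
}
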