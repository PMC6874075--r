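#' Fit a densitometric calibration curve
#'
#' Least-squares line mapping scanner grey values to tissue mineral density,
#' the role of the manufacturer's weekly phantom check (inserts of known
#' equivalent density such as 800, 400, 200, 100 and 0 mg HA/cc).
#'
#' @param grey numeric vector of mean grey values, one per insert.
#' @param density matching known densities in mg HA/cc.
#' @return A `calibration_curve` with `slope` ((mg HA/cc)/grey), `intercept`
#'   (mg HA/cc), `residuals` and the source densities.
#' @export
fit_calibration <- function(grey, density) {
  if (length(grey) != length(density) || length(grey) < 2)
    stop("need at least 2 (grey, density) points")
  if (length(unique(grey)) < 2) stop("grey values must be distinct")
  fit <- stats::lm(density ~ grey)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 residuals = unname(stats::residuals(fit)),
                 source_densities = density),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> TMD = %.6g + %.6g * grey  (mg HA/cc)\n",
              x$intercept, x$slope))
  cat(sprintf("  %d points, max |residual| %.4g mg HA/cc\n",
              length(x$source_densities), max(abs(x$residuals))))
  invisible(x)
}

#' Convert a grey-value image to tissue mineral density
#'
#' Applies the affine calibration per voxel. Negative calibrated densities
#' are clamped to 0 mg HA/cc (density is physically non-negative and the
#' background insert is defined at 0).
#'
#' @param image a grey-valued [voxel_image()].
#' @param curve a [fit_calibration()] result, or a list with `slope` and
#'   `intercept`.
#' @return A [voxel_image()] with `value_kind = "tmd"`.
#' @export
to_tmd <- function(image, curve) {
  stopifnot(inherits(image, "voxel_image"))
  if (image$value_kind != "grey")
    stop("image is already calibrated (value_kind != 'grey')")
  tmd <- curve$intercept + curve$slope * image$data
  tmd[tmd < 0] <- 0
  voxel_image(array(tmd, dim(image$data)), spacing = image$spacing,
              value_kind = "tmd")
}

#' Gaussian kernel weights on the 3x3x3 support
#'
#' Tabulates exp(-r^2 / (2 sigma^2)) over the 27 integer offsets and
#' normalises to sum 1.
#' @param sigma standard deviation in voxel units (default 0.65).
#' @return 3x3x3 numeric array of weights, indexed by x, y, z offset.
#' @export
gaussian_kernel_333 <- function(sigma = 0.65) {
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  w <- exp(-(off$dx^2 + off$dy^2 + off$dz^2) / (2 * sigma^2))
  array(w / sum(w), c(3, 3, 3))
}

#' 3D Gaussian noise filter
#'
#' Discrete Gaussian with sigma = 0.65 voxel truncated to a 3x3x3 support,
#' the standard high-frequency noise filter for in vivo tibia scans. Kernel
#' weights sum to one so constant regions are preserved; borders use
#' replicate padding.
#'
#' @param image a [voxel_image()].
#' @param sigma kernel standard deviation in voxel units.
#' @return Filtered [voxel_image()].
#' @export
gaussian_filter <- function(image, sigma = 0.65) {
  stopifnot(inherits(image, "voxel_image"))
  k <- gaussian_kernel_333(sigma)
  out <- conv333_cpp(image$data, dim(image$data), as.vector(k))
  voxel_image(array(out, dim(image$data)), spacing = image$spacing,
              value_kind = image$value_kind)
}

#' Histogram-based global threshold
#'
#' The segmentation threshold is the average of the grey levels of the bone
#' and background peaks of the image histogram: a 256-bin histogram over the
#' volume of interest is smoothed with a 5-bin moving average, the two most
#' prominent local maxima are located, and the midpoint of their bin centres
#' is returned.
#'
#' @param image a [voxel_image()] (grey or TMD values).
#' @param voi optional [bone_mask()] or logical/0-1 array restricting the
#'   histogram to a volume of interest.
#' @param n_bins number of histogram bins.
#' @param smooth_window moving-average window, bins.
#' @return The threshold (numeric scalar) with attributes `peaks` (the two
#'   peak grey levels, ascending).
#' @export
compute_threshold <- function(image, voi = NULL, n_bins = 256L,
                              smooth_window = 5L) {
  vals <- if (inherits(image, "voxel_image")) image$data else image
  if (!is.null(voi)) vals <- vals[as_mask_array(voi) != 0]
  vals <- as.numeric(vals)
  rng <- range(vals)
  if (diff(rng) <= 0) stop("histogram is degenerate (constant image)")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  counts <- as.numeric(h$counts)
  centers <- h$mids
  # centred moving average (window must be odd)
  hw <- smooth_window %/% 2L
  sm <- stats::filter(counts, rep(1 / smooth_window, smooth_window),
                      sides = 2)
  sm <- as.numeric(sm)
  # edge bins: shrink the window symmetrically
  for (i in seq_len(hw)) {
    sm[i] <- mean(counts[1:(i + hw)])
    j <- n_bins - i + 1L
    sm[j] <- mean(counts[(j - hw):n_bins])
  }
  peaks <- find_peaks(sm)
  if (nrow(peaks) < 2)
    stop("histogram is unimodal; supply a manual threshold")
  top2 <- peaks[order(-peaks$prominence, peaks$index)[1:2], ]
  # a genuine second mode is separated by a deep valley: its prominence is a
  # large fraction of its height; noise wiggles on one mode are not
  if (min(top2$prominence / sm[top2$index]) < 0.5)
    stop("histogram is unimodal; supply a manual threshold")
  pk <- sort(centers[top2$index])
  thr <- mean(pk)
  attr(thr, "peaks") <- pk
  thr
}

# local maxima with prominence (plateau-aware); returns index + prominence
find_peaks <- function(y) {
  n <- length(y)
  idx <- integer(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    left_ok <- i == 1L || y[i - 1L] < y[i]
    right_ok <- j == n || y[j + 1L] < y[i]
    if (left_ok && right_ok)
      idx <- c(idx, as.integer(floor((i + j) / 2)))
    i <- j + 1L
  }
  if (length(idx) == 0) return(data.frame(index = integer(0),
                                          prominence = numeric(0)))
  prom <- vapply(idx, function(p) {
    # key col: the higher of the valley minima separating this peak from
    # strictly higher terrain (or the data end) on each side
    base <- -Inf
    if (p > 1L) {
      hi <- which(y[1:(p - 1L)] > y[p])
      base <- max(base, min(y[if (length(hi)) max(hi):p else 1:p]))
    }
    if (p < n) {
      hi <- which(y[(p + 1L):n] > y[p]) + p
      base <- max(base, min(y[if (length(hi)) p:min(hi) else p:n]))
    }
    if (!is.finite(base)) base <- min(y)
    y[p] - base
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Global single-level segmentation
#'
#' Voxels with value >= threshold are classified as bone (inclusive boundary
#' rule: the threshold value itself belongs to the bone phase).
#'
#' @param image a [voxel_image()].
#' @param threshold grey (or TMD) level.
#' @return A [bone_mask()].
#' @export
segment <- function(image, threshold) {
  stopifnot(inherits(image, "voxel_image"))
  bone_mask(image$data >= threshold, spacing = image$spacing,
            provenance = sprintf("threshold >= %.6g", threshold))
}

#' Remove small disconnected bone volumes
#'
#' Deletes 26-connected 3D components with fewer than `min_size` voxels
#' ("smaller than" is strict: a component of exactly `min_size` voxels is
#' kept).
#'
#' @param mask a [bone_mask()].
#' @param min_size minimum surviving component size, voxels (default 10).
#' @param connectivity 6 or 26 (default 26, whole-3D-volume rule).
#' @return A despeckled [bone_mask()].
#' @export
despeckle <- function(mask, min_size = 10L, connectivity = 26L) {
  m <- as_mask_array(mask)
  lab <- cc_label_cpp(m, dim(m), as.integer(connectivity))
  if (max(lab) == 0) return(bone_mask(m, mask$spacing, "despeckle(empty)"))
  sizes <- tabulate(lab[lab > 0L])
  keep <- sizes >= min_size
  out <- array(0L, dim(m))
  out[lab > 0L][keep[lab[lab > 0L]]] <- 1L
  bone_mask(out, spacing = mask$spacing,
            provenance = sprintf("%s; despeckle(<%d vox, %d-conn)",
                                 mask$provenance, min_size, connectivity))
}

#' Keep only the largest connected component
#'
#' Under the stated connectivity (default 6, the rule used before meshing).
#' Ties are broken deterministically in favour of the component containing
#' the lowest linear voxel index.
#'
#' @param mask a [bone_mask()].
#' @param connectivity 6 or 26.
#' @return A [bone_mask()].
#' @export
largest_component <- function(mask, connectivity = 6L) {
  m <- as_mask_array(mask)
  if (sum(m) == 0) stop("mask is empty")
  lab <- cc_label_cpp(m, dim(m), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0L])
  best <- which.max(sizes) # which.max returns the first (lowest label) on ties
  bone_mask(lab == best, spacing = mask$spacing,
            provenance = sprintf("%s; largest %d-connected component",
                                 mask$provenance, connectivity))
}

disk_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Close intracortical pores, slice by slice
#'
#' Morphological closing with a discrete disk (default radius 10 pixels)
#' applied independently to each transverse (XY) slice, the standard step
#' before cortical area measurements.
#'
#' @param mask a [bone_mask()].
#' @param radius disk radius in pixels.
#' @return A [bone_mask()].
#' @export
close_cortical_pores <- function(mask, radius = 10L) {
  m <- as_mask_array(mask)
  brush <- disk_brush(radius)
  out <- array(0L, dim(m))
  for (k in seq_len(dim(m)[3])) {
    sl <- m[, , k]
    if (!any(sl != 0)) next
    out[, , k] <- as.integer(EBImage::closing(sl, brush) != 0)
  }
  bone_mask(out, spacing = mask$spacing,
            provenance = sprintf("%s; 2D closing r=%d px",
                                 mask$provenance, radius))
}

#' Align the bone's principal axis with z
#'
#' Rotates the grid so the first principal axis of the bone voxel
#' coordinates maps to the longitudinal (z) axis, with the proximal end at
#' low z (the heavier half of the bone, which for a tibia is the proximal
#' epiphysis/metaphysis, is oriented proximally). Left limbs are mirrored
#' across the sagittal (x) plane when `mirror = TRUE` so left and right
#' images share one anatomical frame.
#'
#' @param x a [bone_mask()] or [voxel_image()]; when an image is supplied a
#'   companion mask must be given for axis estimation.
#' @param mask mask used to estimate the axis (defaults to `x` when `x` is a
#'   mask).
#' @param mirror mirror across the sagittal plane (for left limbs).
#' @param proximal `"auto"` (mass-weighted rule above), `"low"` or `"high"`:
#'   which end of the principal axis is proximal before reorientation.
#' @return An object like `x`, resampled into the aligned frame (nearest
#'   neighbour for masks, trilinear for greyscale), with attribute
#'   `transform` (the 3x4 output-to-input affine map, 0-based voxel
#'   coordinates).
#' @export
align_principal_axis <- function(x, mask = NULL, mirror = FALSE,
                                 proximal = c("auto", "low", "high")) {
  proximal <- match.arg(proximal)
  if (is.null(mask)) {
    if (!inherits(x, "bone_mask"))
      stop("supply `mask` when aligning a greyscale image")
    mask <- x
  }
  m <- as_mask_array(mask)
  idx <- which(m != 0)
  if (length(idx) < 10) stop("mask too small to define a principal axis")
  d <- dim(m)
  co <- arrayInd(idx, d) - 1 # 0-based voxel coordinates
  co <- matrix(as.numeric(co), ncol = 3)
  ctr <- colMeans(co)
  cc <- sweep(co, 2, ctr)
  ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
  if (ev$values[1] < 1.05 * ev$values[2])
    stop("no dominant principal axis (isotropic blob)")
  a3 <- ev$vectors[, 1] # longitudinal
  # decide sign: proximal (heavier) end at low z
  s <- cc %*% a3
  if (proximal == "auto") {
    # the wider (heavier) end is proximal: positive skew along the axis means
    # the long thin tail points to high s, i.e. the heavy end sits at low s,
    # which is already the proximal convention; negative skew requires a flip
    if (mean(s^3) / stats::sd(s)^3 < 0) a3 <- -a3
    s <- cc %*% a3
  } else if (proximal == "high") {
    a3 <- -a3
    s <- cc %*% a3
  }
  # complete a right-handed orthonormal basis (a1 -> x, a2 -> y, a3 -> z)
  ref <- if (abs(a3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- ref - sum(ref * a3) * a3
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(a3[2] * a1[3] - a3[3] * a1[2],
          a3[3] * a1[1] - a3[1] * a1[3],
          a3[1] * a1[2] - a3[2] * a1[1])
  R <- rbind(a1, a2, a3) # maps input-centred coords to aligned coords
  # output grid: same dims (package convention keeps grid shape)
  out_dims <- d
  out_ctr <- (out_dims - 1) / 2
  # output voxel -> input voxel: p_in = ctr + t(R) %*% (p_out - out_ctr)
  A <- cbind(t(R), ctr - t(R) %*% out_ctr)
  if (mirror) {
    # mirror across the sagittal plane: flip output x before mapping
    Mx <- cbind(diag(c(-1, 1, 1)), c(out_dims[1] - 1, 0, 0))
    # compose: p_in = A %*% [Mx p_out; 1]
    A <- cbind(A[, 1:3] %*% Mx[, 1:3], A[, 1:3] %*% Mx[, 4] + A[, 4])
  }
  if (inherits(x, "bone_mask")) {
    out <- resample_affine_cpp(x$data + 0.0, d, A, out_dims, 0L, 0.0)
    res <- bone_mask(array(out, out_dims) != 0, spacing = x$spacing,
                     provenance = paste0(x$provenance, "; principal-axis aligned",
                                         if (mirror) ", mirrored" else ""))
  } else {
    out <- resample_affine_cpp(x$data, d, A, out_dims, 1L, min(x$data))
    res <- voxel_image(array(out, out_dims), spacing = x$spacing,
                       value_kind = x$value_kind)
  }
  attr(res, "transform") <- A
  res
}

#' Tibia length
#'
#' Distance between the most proximal and most distal bone voxels along z,
#' using the slab convention: `(z_last - z_first + 1) * spacing`, so a
#' single-slice object is one voxel spacing long. Reported in mm.
#'
#' @param mask an aligned [bone_mask()].
#' @param spacing voxel spacing, micrometres; defaults to the mask's.
#' @return Length in mm.
#' @export
tibia_length <- function(mask, spacing = NULL) {
  m <- as_mask_array(mask)
  if (is.null(spacing)) spacing <- mask$spacing
  zs <- which(apply(m, 3, function(sl) any(sl != 0)))
  if (length(zs) == 0) stop("mask is empty")
  (max(zs) - min(zs) + 1) * spacing / 1000
}
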