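#' Extract the trabecular volume of interest
#'
#' Selects the slab of slices starting `offset_mm` distal to the reference
#' slice (the growth-plate merge point) and spanning `height_mm`, then
#' removes the cortical shell with an automatic endosteal contour: per slice,
#' the periosteal boundary is filled, the fill is eroded by the estimated
#' shell thickness (plus a safety margin), and only bone inside the eroded
#' interior is kept. Slices without a closed shell are kept whole.
#'
#' @param mask an aligned [bone_mask()].
#' @param ref_slice reference slice index (1-based).
#' @param offset_mm distal offset from the reference slice (default 0.2).
#' @param height_mm VOI height (default 1.0).
#' @return An object of class `trabecular_voi`: `bone` (trabecular bone
#'   mask), `region` (the VOI region the bone sits in, used as the
#'   denominator for BV/TV and as the domain for separation), and `slices`.
#' @export
extract_trabecular_voi <- function(mask, ref_slice, offset_mm = 0.2,
                                   height_mm = 1.0) {
  m <- as_mask_array(mask)
  sp_mm <- mask$spacing / 1000
  start <- ref_slice + round(offset_mm / sp_mm)
  n <- round(height_mm / sp_mm)
  stop_slice <- start + n - 1L
  if (start < 1 || stop_slice > dim(m)[3])
    stop("trabecular VOI exceeds image extent")
  slices <- start:stop_slice
  sub <- m[, , slices, drop = FALSE]
  bone <- array(0L, dim(sub))
  region <- array(0L, dim(sub))
  for (k in seq_along(slices)) {
    sl <- sub[, , k]
    interior <- endosteal_interior(sl)
    bone[, , k] <- as.integer(sl != 0 & interior)
    region[, , k] <- as.integer(interior)
  }
  structure(list(bone = bone_mask(bone, mask$spacing, "trabecular VOI"),
                 region = bone_mask(region, mask$spacing, "trabecular VOI region"),
                 slices = slices),
            class = "trabecular_voi")
}

# Per-slice endosteal interior: detect the cortical shell (the 2D component
# whose filled hull gains the most area), erode its hull past the shell, and
# return a logical matrix. If no closed shell is present, the whole slice is
# the interior.
endosteal_interior <- function(sl) {
  d <- dim(sl)
  if (!any(sl != 0)) return(matrix(TRUE, d[1], d[2]))
  lab <- EBImage::bwlabel(sl)
  nlab <- max(lab)
  gains <- numeric(nlab)
  fills <- vector("list", nlab)
  for (l in seq_len(nlab)) {
    comp <- (lab == l) * 1
    filled <- EBImage::fillHull(comp)
    fills[[l]] <- filled
    gains[l] <- sum(filled) - sum(comp)
  }
  best <- which.max(gains)
  filled <- fills[[best]]
  if (gains[best] < 0.25 * sum(filled)) return(matrix(TRUE, d[1], d[2]))
  shell <- (lab == best) * 1
  dt <- EBImage::distmap(shell)
  ct_px <- ceiling(2 * max(dt)) + 1L
  interior <- EBImage::erode(filled, disk_brush(ct_px))
  as.matrix(interior) != 0
}

#' Bone volume fraction
#'
#' @param phase bone-phase mask (subset of `total`).
#' @param total total-region mask.
#' @return BV/TV in percent: `100 * |phase| / |total|`.
#' @export
bvtv <- function(phase, total) {
  p <- as_mask_array(phase)
  t <- as_mask_array(total)
  if (sum(t) == 0) stop("total region is empty")
  if (any(p > t)) stop("phase must be a subset of the total region")
  100 * sum(p) / sum(t)
}

#' Model-independent local thickness map
#'
#' Thickness at a voxel is the diameter of the largest sphere fully
#' contained in the phase that covers the voxel (maximal-sphere definition),
#' computed from the exact Euclidean distance transform with distance-ridge
#' sphere propagation.
#'
#' @param mask a [bone_mask()] (or 0/1 array).
#' @param spacing voxel spacing in micrometres; defaults to the mask's.
#' @return A [voxel_image()] of per-voxel thickness in micrometres (0 on
#'   background).
#' @export
local_thickness <- function(mask, spacing = NULL) {
  m <- as_mask_array(mask)
  if (sum(m) == 0) stop("mask is empty")
  if (is.null(spacing))
    spacing <- if (inherits(mask, "bone_mask")) mask$spacing else 1
  th <- local_thickness_cpp(m, dim(m))
  voxel_image(array(th * spacing, dim(m)), spacing = spacing, "grey")
}

#' Mean trabecular thickness
#'
#' Volume-weighted mean of the local thickness over the bone phase, in
#' micrometres.
#'
#' @param voi a `trabecular_voi` from [extract_trabecular_voi()], or a
#'   [bone_mask()].
#' @return Tb.Th in micrometres.
#' @export
tb_th <- function(voi) {
  mask <- if (inherits(voi, "trabecular_voi")) voi$bone else voi
  m <- as_mask_array(mask)
  if (sum(m) == 0) stop("bone phase is empty")
  th <- local_thickness(mask)$data
  mean(th[m != 0])
}

#' Mean trabecular separation
#'
#' Volume-weighted mean local thickness of the background (marrow) phase
#' restricted to the VOI region, in micrometres.
#'
#' @param voi a `trabecular_voi` from [extract_trabecular_voi()].
#' @return Tb.Sp in micrometres.
#' @export
tb_sp <- function(voi) {
  stopifnot(inherits(voi, "trabecular_voi"))
  comp <- voi$region$data * (1L - voi$bone$data)
  if (sum(comp) == 0) stop("background phase is empty")
  cm <- bone_mask(comp, voi$bone$spacing)
  th <- local_thickness(cm)$data
  mean(th[comp != 0])
}

#' Trabecular number
#'
#' Plate-model ratio `Tb.N = (BV/TV) / Tb.Th`.
#'
#' @param bvtv_pct bone volume fraction, percent.
#' @param tb_th_um mean trabecular thickness, micrometres.
#' @return Tb.N in 1/mm.
#' @export
tb_n <- function(bvtv_pct, tb_th_um) {
  if (bvtv_pct == 0) return(0)
  if (tb_th_um <= 0) stop("Tb.Th must be positive")
  (bvtv_pct / 100) / (tb_th_um / 1000)
}

#' Trabecular metrics from a VOI
#'
#' @param voi a `trabecular_voi`.
#' @return A one-row data.frame with `Tb.BV/TV` (%), `Tb.Th` (um),
#'   `Tb.Sp` (um) and `Tb.N` (1/mm).
#' @export
trabecular_metrics <- function(voi) {
  stopifnot(inherits(voi, "trabecular_voi"))
  bv <- bvtv(voi$bone, voi$region)
  th <- tb_th(voi)
  sp <- tb_sp(voi)
  data.frame(`Tb.BV/TV` = bv, `Tb.Th` = th, `Tb.Sp` = sp,
             `Tb.N` = tb_n(bv, th), check.names = FALSE)
}

#' Cortical metrics at the midshaft
#'
#' Selects a VOI of `height_mm` centred at the midshaft (50% of the computed
#' tibia length), closes intracortical pores slice by slice
#' ([close_cortical_pores()]), and measures per slice the filled periosteal
#' area (Tt.Ar) and closed bone area (Ct.Ar); Ct.Th is the mean 3D local
#' thickness of the closed cortical phase in the VOI. An open (non-annular)
#' cross-section raises a warning; areas are still computed.
#'
#' @param mask an aligned [bone_mask()].
#' @param height_mm VOI height (default 1.0).
#' @param closing_radius pore-closing disk radius, pixels.
#' @param midshaft_slice optional override of the central slice.
#' @return A one-row data.frame: `Tt.Ar` (mm^2), `Ct.Ar` (mm^2),
#'   `Ct.Ar/Tt.Ar` (%), `Ct.Th` (um).
#' @export
cortical_metrics <- function(mask, height_mm = 1.0, closing_radius = 10L,
                             midshaft_slice = NULL) {
  m <- as_mask_array(mask)
  sp_mm <- mask$spacing / 1000
  zs <- which(apply(m, 3, function(sl) any(sl != 0)))
  if (length(zs) == 0) stop("mask is empty")
  if (is.null(midshaft_slice))
    midshaft_slice <- round((min(zs) + max(zs)) / 2)
  half <- round(height_mm / sp_mm / 2)
  slices <- max(1, midshaft_slice - half):min(dim(m)[3],
                                              midshaft_slice + half - 1)
  sub <- bone_mask(m[, , slices, drop = FALSE], mask$spacing)
  closed <- close_cortical_pores(sub, radius = closing_radius)
  tt <- ct <- numeric(length(slices))
  open_flagged <- FALSE
  for (k in seq_along(slices)) {
    sl <- closed$data[, , k]
    filled <- as.matrix(EBImage::fillHull(sl)) != 0
    tt[k] <- sum(filled)
    ct[k] <- sum(sl != 0)
    if (tt[k] > 0 && tt[k] == ct[k]) {
      # no enclosed canal: either a solid section (fine) or an open arc.
      # An arc is much thinner than its lateral extent.
      dt2 <- EBImage::distmap(sl)
      ext <- max(diff(range(which(rowSums(sl) > 0))),
                 diff(range(which(colSums(sl) > 0)))) + 1
      if (2 * max(dt2) < 0.4 * ext) open_flagged <- TRUE
    }
  }
  if (open_flagged)
    warning("open (non-annular) cortical cross-section in the VOI; ",
            "areas computed on the open section")
  th <- local_thickness(closed)$data
  ct_th <- mean(th[closed$data != 0])
  ttar <- mean(tt) * sp_mm^2
  ctar <- mean(ct) * sp_mm^2
  data.frame(`Tt.Ar` = ttar, `Ct.Ar` = ctar,
             `Ct.Ar/Tt.Ar` = 100 * ctar / ttar, `Ct.Th` = ct_th,
             check.names = FALSE)
}
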