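#' Densitometric volume of interest
#'
#' Starting at the first slice distal to the growth plate (supplied as
#' `start_slice`), the VOI spans 80% of the total tibia length. The fibula
#' is excluded by a per-slice connected-component rule: the tibial region is
#' seeded at the proximal slice (largest 2D component plus everything inside
#' its filled hull) and propagated slice by slice, keeping components that
#' overlap the slightly dilated filled hull of the previous slice's tibial
#' region.
#'
#' @param mask an aligned [bone_mask()].
#' @param start_slice proximal start of the VOI (1-based slice index).
#' @param fraction fraction of the tibia length covered (default 0.8).
#' @return A list of class `densito_voi`: `bone` (tibia-only mask over the
#'   VOI slices), `slices`, `n_excluded` (voxels removed as non-tibia).
#' @export
densitometric_voi <- function(mask, start_slice, fraction = 0.8) {
  m <- as_mask_array(mask)
  len_mm <- tibia_length(mask)
  sp_mm <- mask$spacing / 1000
  n <- round(fraction * len_mm / sp_mm)
  stop_slice <- start_slice + n - 1L
  if (start_slice < 1 || stop_slice > dim(m)[3])
    stop("densitometric VOI exceeds image extent")
  slices <- start_slice:stop_slice
  sub <- m[, , slices, drop = FALSE]
  out <- array(0L, dim(sub))
  prev_hull <- NULL
  n_excluded <- 0L
  for (k in seq_along(slices)) {
    sl <- sub[, , k]
    if (!any(sl != 0)) { prev_hull <- NULL; next }
    lab <- EBImage::bwlabel(sl)
    nlab <- max(lab)
    sizes <- tabulate(lab[lab > 0L], nbins = nlab)
    if (is.null(prev_hull)) {
      seedc <- which.max(sizes)
      hull <- as.matrix(EBImage::fillHull((lab == seedc) * 1)) != 0
      keep <- vapply(seq_len(nlab),
                     function(l) any(hull[lab == l]) || l == seedc,
                     logical(1))
    } else {
      keep <- vapply(seq_len(nlab),
                     function(l) any(prev_hull[lab == l]), logical(1))
      if (!any(keep)) keep[which.max(sizes)] <- TRUE
    }
    tib <- array(0L, dim(sl))
    for (l in which(keep)) tib[lab == l] <- 1L
    n_excluded <- n_excluded + sum(sl != 0) - sum(tib)
    out[, , k] <- tib
    hull <- as.matrix(EBImage::fillHull(tib)) != 0
    prev_hull <- as.matrix(EBImage::dilate(hull * 1, disk_brush(2L))) != 0
  }
  structure(list(bone = bone_mask(out, mask$spacing, "densitometric VOI"),
                 slices = slices, n_excluded = n_excluded),
            class = "densito_voi")
}

#' Partition the densitometric VOI into 40 regions
#'
#' Ten equal longitudinal sections (remainder slices assigned to the most
#' distal section, section 01 proximal) crossed with four quadrants split by
#' the two vertical planes through each section's bone centroid at +-45
#' degrees to the image x axis. The quadrant labels map image directions to
#' anatomical directions via `orientation`: the default labels the sectors
#' centred on +x, +y, -x, -y as lateral, anterior, medial, posterior.
#' Partitions are disjoint and cover the VOI slab exactly (every voxel of
#' every VOI slice gets a section and quadrant).
#'
#' @param voi a `densito_voi` from [densitometric_voi()].
#' @param n_sections number of longitudinal sections (default 10).
#' @param orientation length-4 character vector labelling the sectors centred
#'   on +x, +y, -x, -y.
#' @return A list of class `partition_grid`: `section` and `quadrant`
#'   integer arrays over the VOI slab, `quadrant_labels`, `slices`.
#' @export
partition_voi <- function(voi, n_sections = 10L,
                          orientation = c("L", "A", "M", "P")) {
  stopifnot(inherits(voi, "densito_voi"), length(orientation) == 4)
  m <- voi$bone$data
  d <- dim(m)
  nsl <- d[3]
  if (nsl < n_sections) stop("VOI has fewer slices than sections")
  base <- nsl %/% n_sections
  sec_of_slice <- c(rep(seq_len(n_sections), each = base),
                    rep(n_sections, nsl - base * n_sections))
  section <- array(0L, d)
  quadrant <- array(0L, d)
  xs <- seq_len(d[1])
  ys <- seq_len(d[2])
  xg <- matrix(xs, d[1], d[2])
  yg <- matrix(ys, d[1], d[2], byrow = TRUE)
  for (s in seq_len(n_sections)) {
    ks <- which(sec_of_slice == s)
    sub <- m[, , ks, drop = FALSE]
    if (sum(sub) == 0) stop("empty section ", s, " in partition grid")
    idx <- which(sub != 0)
    co <- arrayInd(idx, dim(sub))
    cxy <- c(mean(co[, 1]), mean(co[, 2]))
    theta <- atan2(yg - cxy[2], xg - cxy[1])
    sector <- (floor((theta + pi / 4) / (pi / 2)) %% 4) + 1L
    for (k in ks) {
      section[, , k] <- s
      quadrant[, , k] <- sector
    }
  }
  structure(list(section = section, quadrant = quadrant,
                 quadrant_labels = orientation, slices = voi$slices,
                 n_sections = as.integer(n_sections)),
            class = "partition_grid")
}

#' Densitometric metrics per partition
#'
#' For each of the 40 partitions: BMC (mg) as the sum over bone voxels of
#' TMD times the voxel volume; TMD (mg HA/cc) as the mean over bone voxels
#' (NA when the partition holds no bone); BMD (mg HA/cc) as BMC divided by
#' the total partition volume; and BV/TV (%) as bone voxels over partition
#' voxels.
#'
#' @param tmd a calibrated [voxel_image()] (`value_kind == "tmd"`) covering
#'   the same grid as the original mask.
#' @param voi a `densito_voi` (its bone mask defines the bone phase).
#' @param grid a `partition_grid` from [partition_voi()].
#' @return A data.frame with 40 rows: `section` ("01".."10"), `quadrant`,
#'   `BMC_mg`, `TMD`, `BMD`, `BVTV`.
#' @export
partition_metrics <- function(tmd, voi, grid) {
  stopifnot(inherits(tmd, "voxel_image"), tmd$value_kind == "tmd",
            inherits(voi, "densito_voi"), inherits(grid, "partition_grid"))
  sub_tmd <- tmd$data[, , voi$slices, drop = FALSE]
  bone <- voi$bone$data
  v_cm3 <- (tmd$spacing * 1e-4)^3
  nq <- 4L
  ns <- grid$n_sections
  part_id <- (grid$section - 1L) * nq + grid$quadrant
  nparts <- ns * nq
  npart_vox <- tabulate(part_id, nbins = nparts)
  bone_id <- part_id[bone != 0]
  nbone <- tabulate(bone_id, nbins = nparts)
  bmc_sum <- rep(0, nparts)
  sums <- tapply(sub_tmd[bone != 0], bone_id, sum)
  bmc_sum[as.integer(names(sums))] <- sums
  bmc <- bmc_sum * v_cm3
  tmd_mean <- ifelse(nbone > 0, bmc_sum / nbone, NA_real_)
  bmd <- bmc / (npart_vox * v_cm3)
  bvtv_p <- 100 * nbone / npart_vox
  sec <- rep(seq_len(ns), each = nq)
  quad <- rep(seq_len(nq), times = ns)
  data.frame(section = sprintf("%02d", sec),
             quadrant = grid$quadrant_labels[quad],
             BMC_mg = bmc, TMD = tmd_mean, BMD = bmd, BVTV = bvtv_p,
             stringsAsFactors = FALSE)
}

#' Total bone mineral content
#'
#' @param tmd calibrated [voxel_image()].
#' @param mask bone mask on the same grid (or a `densito_voi`).
#' @param slices optional slice range when `mask` covers only a sub-slab.
#' @return Total BMC in mg.
#' @export
total_bmc <- function(tmd, mask, slices = NULL) {
  if (inherits(mask, "densito_voi")) {
    slices <- mask$slices
    mask <- mask$bone
  }
  m <- as_mask_array(mask)
  vals <- if (is.null(slices)) tmd$data else tmd$data[, , slices, drop = FALSE]
  sum(vals[m != 0]) * (tmd$spacing * 1e-4)^3
}

#' Paired partition percent differences
#'
#' Per partition and metric, `100 * (right - left) / left`; partitions with a
#' zero left value give NA.
#'
#' @param left,right partition tables from [partition_metrics()] on matching
#'   grids.
#' @return A data.frame with `section`, `quadrant` and percent differences
#'   for `BMC_mg`, `TMD`, `BMD`, `BVTV`.
#' @export
paired_partition_difference <- function(left, right) {
  if (!identical(left$section, right$section) ||
      !identical(left$quadrant, right$quadrant))
    stop("partition tables do not share a grid")
  pd <- function(l, r) ifelse(is.na(l) | l == 0, NA_real_, 100 * (r - l) / l)
  data.frame(section = left$section, quadrant = left$quadrant,
             BMC_mg = pd(left$BMC_mg, right$BMC_mg),
             TMD = pd(left$TMD, right$TMD),
             BMD = pd(left$BMD, right$BMD),
             BVTV = pd(left$BVTV, right$BVTV),
             stringsAsFactors = FALSE)
}

#' Cohort summary of partition differences
#'
#' Median and standard deviation across mice of the per-mouse paired percent
#' differences, per partition (the reporting convention for spatial BMC
#' maps).
#'
#' @param diff_tables list of [paired_partition_difference()] outputs, one
#'   per mouse.
#' @param metric column to summarise (default `"BMC_mg"`).
#' @return A data.frame: `section`, `quadrant`, `median`, `sd`, `n`.
#' @export
partition_cohort_summary <- function(diff_tables, metric = "BMC_mg") {
  stopifnot(length(diff_tables) >= 1)
  vals <- vapply(diff_tables, function(d) d[[metric]],
                 numeric(nrow(diff_tables[[1]])))
  vals <- matrix(vals, nrow = nrow(diff_tables[[1]]))
  data.frame(section = diff_tables[[1]]$section,
             quadrant = diff_tables[[1]]$quadrant,
             median = apply(vals, 1, stats::median, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n = apply(vals, 1, function(v) sum(!is.na(v))),
             stringsAsFactors = FALSE)
}
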