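#' Radiation effect specification for phantom pairs
#'
#' Percent changes applied to the right (irradiated) phantom of a pair,
#' emulating the within-mouse radiation effects seen in paired-limb mouse
#' tibia studies (e.g. a -14.2% change in trabecular number).
#'
#' @param delta_tb_n_pct percent change in trabecular rod count.
#' @param delta_tb_th_pct percent change in rod thickness.
#' @param delta_tt_ar_pct percent change in periosteal (total) cross-sectional
#'   area.
#' @return An object of class `radiation_effect`.
#' @export
radiation_effect <- function(delta_tb_n_pct = 0, delta_tb_th_pct = 0,
                             delta_tt_ar_pct = 0) {
  for (d in c(delta_tb_n_pct, delta_tb_th_pct, delta_tt_ar_pct))
    if (!is.finite(d) || d <= -100)
      stop("percent changes must be finite and > -100")
  structure(list(delta_tb_n_pct = delta_tb_n_pct,
                 delta_tb_th_pct = delta_tb_th_pct,
                 delta_tt_ar_pct = delta_tt_ar_pct),
            class = "radiation_effect")
}

#' Synthetic tibia phantom specification
#'
#' Defines a scaled-down tibia-like object: a cortical shell with a medullary
#' canal whose periosteal radius and wall thickness vary along the bone, and
#' a proximal lattice of longitudinal trabecular rods on a jittered grid with
#' analytic ground truth. Defaults emulate in vivo mouse tibia scans at
#' 10.4 um voxels, with realistic trabecular dimensions (rod diameter 52 um;
#' after filtering and thresholding the standard chain measures Tb.Th ~40 um,
#' BV/TV ~10% and Tb.N ~2.5/mm in the trabecular VOI)
#' in a ~4.2 mm long miniature bone that keeps image sizes tractable while
#' separating the proximal trabecular compartment from the midshaft.
#'
#' @param dim image dimensions `[x, y, z]` in voxels.
#' @param spacing voxel spacing, micrometres.
#' @param outer_radius_profile data.frame with `z_mm` and `radius_um`:
#'   periosteal radius versus longitudinal position, interpolated linearly.
#' @param cortical_thickness_profile data.frame with `z_mm`, `thickness_um`.
#' @param trabecular_zrange_mm longitudinal extent of the rod lattice, mm.
#' @param rod_thickness rod diameter, micrometres.
#' @param rod_spacing lattice pitch, micrometres (must exceed
#'   `rod_thickness`).
#' @param canal_margin_um clearance kept between rods and the endosteal
#'   surface.
#' @param tissue_density mineral density of bone tissue, mg HA/cc.
#' @param background_density density of the background/marrow phase.
#' @param noise_sd additive Gaussian noise, grey units (detector noise is
#'   added in grey values, before calibration).
#' @param grey_slope,grey_intercept calibration mapping
#'   `TMD = intercept + slope * grey`.
#' @param ref_slice reference slice index (growth-plate merge point) carried
#'   as ground truth for VOI placement.
#' @param effect a [radiation_effect()] applied to the right phantom.
#' @param fibula add a separate off-axis rod mimicking the fibula (used to
#'   exercise the fibula-exclusion rule); requires a wide enough image.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(108L, 108L, 400L),
                         spacing = 10.4,
                         outer_radius_profile = data.frame(
                           z_mm = c(0, 1.5, 2.1, 3.4),
                           radius_um = c(480, 460, 380, 340)),
                         cortical_thickness_profile = data.frame(
                           z_mm = c(0, 1.5, 2.1, 3.4),
                           thickness_um = c(80, 80, 230, 200)),
                         trabecular_zrange_mm = c(0.10, 1.45),
                         rod_thickness = 52,
                         rod_spacing = 130,
                         canal_margin_um = 50,
                         tissue_density = 720,
                         background_density = 0,
                         noise_sd = 150,
                         grey_slope = 0.5,
                         grey_intercept = 0,
                         ref_slice = 11L,
                         effect = radiation_effect(),
                         fibula = FALSE,
                         seed = 1L) {
  stopifnot(length(dim) == 3, all(dim >= 1), spacing > 0, noise_sd >= 0,
            rod_thickness < rod_spacing, grey_slope != 0)
  rz <- function(z_mm) stats::approx(outer_radius_profile$z_mm,
                                     outer_radius_profile$radius_um,
                                     z_mm, rule = 2)$y
  ct <- function(z_mm) stats::approx(cortical_thickness_profile$z_mm,
                                     cortical_thickness_profile$thickness_um,
                                     z_mm, rule = 2)$y
  zs <- (seq_len(dim[3]) - 1) * spacing / 1000
  if (any(rz(zs) <= ct(zs)))
    stop("outer radius must exceed cortical thickness everywhere")
  if (2 * max(rz(zs)) / spacing > min(dim[1:2]) - 4)
    stop("image too small to contain the phantom geometry")
  structure(list(dim = as.integer(dim), spacing = spacing,
                 outer_radius_profile = outer_radius_profile,
                 cortical_thickness_profile = cortical_thickness_profile,
                 trabecular_zrange_mm = trabecular_zrange_mm,
                 rod_thickness = rod_thickness, rod_spacing = rod_spacing,
                 canal_margin_um = canal_margin_um,
                 tissue_density = tissue_density,
                 background_density = background_density,
                 noise_sd = noise_sd, grey_slope = grey_slope,
                 grey_intercept = grey_intercept,
                 ref_slice = as.integer(ref_slice), effect = effect,
                 fibula = fibula, seed = as.integer(seed)),
            class = "phantom_spec")
}

profile_fun <- function(df, ycol) {
  function(z_mm) stats::approx(df$z_mm, df[[ycol]], z_mm, rule = 2)$y
}

# Lay out the rod lattice once for a spec (jittered square grid inside the
# narrowest canal cross-section of the trabecular region). Returns centres in
# micrometres relative to the bone axis.
plan_rods <- function(spec) {
  orp <- profile_fun(spec$outer_radius_profile, "radius_um")
  ctp <- profile_fun(spec$cortical_thickness_profile, "thickness_um")
  zr <- spec$trabecular_zrange_mm
  zz <- seq(zr[1], zr[2], length.out = 64)
  canal_min <- min(orp(zz) - ctp(zz))
  allowed <- canal_min - spec$canal_margin_um - spec$rod_thickness / 2
  if (allowed <= 0) stop("canal too narrow for the rod lattice")
  s <- spec$rod_spacing
  half <- ceiling(allowed / s) + 1
  g <- (seq(-half, half) + 0.5) * s
  pos <- as.matrix(expand.grid(x = g, y = g))
  jit <- matrix(stats::runif(length(pos), -0.25 * s, 0.25 * s), ncol = 2)
  pos <- pos + jit
  keep <- sqrt(rowSums(pos^2)) <= allowed
  pos[keep, , drop = FALSE]
}

# Voxelize one side. `rods` in um (axis-relative), rod_radius_um scalar,
# outer radius scale applied multiplicatively. Labels: 0 background,
# 1 cortex, 2 trabecular rod, 3 fibula.
voxelize_phantom <- function(spec, rods, rod_radius_um, outer_scale = 1) {
  d <- spec$dim
  sp <- spec$spacing
  orp <- profile_fun(spec$outer_radius_profile, "radius_um")
  ctp <- profile_fun(spec$cortical_thickness_profile, "thickness_um")
  cx <- (d[1] - 1) / 2
  cy <- (d[2] - 1) / 2
  xs <- ((seq_len(d[1]) - 1) - cx) * sp
  ys <- ((seq_len(d[2]) - 1) - cy) * sp
  rho <- sqrt(outer(xs^2, ys^2, `+`))
  rod2d <- matrix(FALSE, d[1], d[2])
  if (nrow(rods) > 0) {
    for (i in seq_len(nrow(rods))) {
      rr <- sqrt(outer((xs - rods[i, 1])^2, (ys - rods[i, 2])^2, `+`))
      rod2d <- rod2d | (rr <= rod_radius_um)
    }
  }
  fib2d <- matrix(FALSE, d[1], d[2])
  fib_r <- 60
  if (isTRUE(spec$fibula)) {
    fib_off <- max(orp(0), orp(3)) * outer_scale + 150
    if ((cx * sp - fib_off) < fib_r + 2 * sp)
      stop("image too small to contain the fibula rod")
    rr <- sqrt(outer((xs - fib_off)^2, (ys - 0)^2, `+`))
    fib2d <- rr <= fib_r
  }
  zr_vox <- spec$trabecular_zrange_mm * 1000 / sp + 1 # 1-based slices
  lab <- array(0L, d)
  for (k in seq_len(d[3])) {
    z_mm <- (k - 1) * sp / 1000
    R <- orp(z_mm) * outer_scale
    r_in <- R - ctp(z_mm)
    sl <- matrix(0L, d[1], d[2])
    sl[rho <= R & rho > r_in] <- 1L
    if (k >= zr_vox[1] && k <= zr_vox[2]) sl[rod2d & sl == 0L] <- 2L
    if (isTRUE(spec$fibula) && z_mm >= 0.3) sl[fib2d] <- 3L
    lab[, , k] <- sl
  }
  lab
}

flip_x <- function(arr) arr[rev(seq_len(dim(arr)[1])), , , drop = FALSE]

#' Generate a paired left/right tibia phantom
#'
#' The left phantom is generated from the spec; the right phantom shares its
#' geometry mirrored across the sagittal plane, with the spec's
#' [radiation_effect()] applied (rod count scaled and rounded, rod thickness
#' and periosteal area scaled) and an independent noise realisation. With a
#' zero effect and zero noise the right image is exactly the voxelwise mirror
#' of the left one.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `left` and `right` [voxel_image()]s and `truth`, a
#'   list of per-side ground truth (`labels` arrays with 0 = background,
#'   1 = cortex, 2 = rod, 3 = fibula; rod count, centres and diameter;
#'   reference slice; trabecular slice range; tissue density; calibration).
#' @export
generate_tibia_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  rods_l <- plan_rods(spec)
  n_l <- nrow(rods_l)
  if (n_l < 1) stop("no rods fit the canal; enlarge the geometry")
  eff <- spec$effect
  n_r <- round(n_l * (1 + eff$delta_tb_n_pct / 100))
  if (n_r <= n_l) {
    keep <- sample.int(n_l, n_r)
    rods_r <- rods_l[sort(keep), , drop = FALSE]
  } else {
    extra <- plan_rods(spec) # fresh jitter for additional rods
    new_idx <- sample.int(nrow(extra), min(n_r - n_l, nrow(extra)))
    rods_r <- rbind(rods_l, extra[new_idx, , drop = FALSE])
  }
  rad_l <- spec$rod_thickness / 2
  rad_r <- rad_l * (1 + eff$delta_tb_th_pct / 100)
  scale_r <- sqrt(1 + eff$delta_tt_ar_pct / 100)

  lab_l <- voxelize_phantom(spec, rods_l, rad_l, 1)
  lab_r0 <- voxelize_phantom(spec, rods_r, rad_r, scale_r)
  lab_r <- flip_x(lab_r0)

  dens <- function(lab) {
    out <- array(spec$background_density, dim(lab))
    out[lab > 0L] <- spec$tissue_density
    out
  }
  grey <- function(density_arr) {
    g <- (density_arr - spec$grey_intercept) / spec$grey_slope
    if (spec$noise_sd > 0)
      g <- g + stats::rnorm(length(g), 0, spec$noise_sd)
    array(g, dim(density_arr))
  }
  left <- voxel_image(grey(dens(lab_l)), spacing = spec$spacing, "grey")
  right <- voxel_image(grey(dens(lab_r)), spacing = spec$spacing, "grey")

  mk_truth <- function(lab, rods, rad, n, scale) {
    orp <- profile_fun(spec$outer_radius_profile, "radius_um")
    list(labels = lab,
         rod_count = n,
         rod_centers_um = rods,
         rod_diameter_um = 2 * rad,
         ref_slice = spec$ref_slice,
         trab_slice_range = round(spec$trabecular_zrange_mm * 1000 /
                                    spec$spacing + 1),
         tissue_density = spec$tissue_density,
         outer_scale = scale,
         tt_ar_mm2_analytic = function(z_mm)
           pi * (orp(z_mm) * scale / 1000)^2,
         grey_slope = spec$grey_slope,
         grey_intercept = spec$grey_intercept,
         spacing = spec$spacing)
  }
  list(left = left, right = right,
       truth = list(left = mk_truth(lab_l, rods_l, rad_l, n_l, 1),
                    right = mk_truth(lab_r, rods_r, rad_r, nrow(rods_r),
                                     scale_r)))
}

#' Generate a densitometric calibration phantom
#'
#' One homogeneous cylindrical insert per requested density, mimicking the
#' scanner's weekly quality-check phantom (e.g. 800, 400, 200, 100 and 0
#' mg HA/cc), with grey values produced by the inverse calibration plus
#' optional Gaussian noise.
#'
#' @param densities known insert densities, mg HA/cc (at least two,
#'   all distinct).
#' @param grey_slope,grey_intercept calibration `TMD = intercept +
#'   slope * grey`.
#' @param noise_sd additive Gaussian noise, grey units.
#' @param seed integer seed.
#' @param insert_radius_px,insert_pitch_px,ny,nz layout controls.
#' @return A list: `image` (a [voxel_image()]) and `truth` (per-insert voxel
#'   index list, densities, and the generating line).
#' @export
generate_calibration_phantom <- function(densities = c(800, 400, 200, 100, 0),
                                         grey_slope = 0.5,
                                         grey_intercept = 0,
                                         noise_sd = 0, seed = 1L,
                                         insert_radius_px = 5L,
                                         insert_pitch_px = 16L,
                                         ny = 24L, nz = 8L) {
  if (length(densities) < 2) stop("need at least two densities")
  if (anyDuplicated(densities)) stop("densities must be distinct")
  k <- length(densities)
  nx <- k * insert_pitch_px
  arr <- array(0, c(nx, ny, nz))
  centers_x <- (seq_len(k) - 0.5) * insert_pitch_px
  cy <- (ny + 1) / 2
  inserts <- vector("list", k)
  xs <- seq_len(nx)
  ysq <- (seq_len(ny) - cy)^2
  for (i in seq_len(k)) {
    d2 <- outer((xs - centers_x[i])^2, ysq, `+`)
    in2d <- d2 <= insert_radius_px^2
    idx3 <- which(array(in2d, c(nx, ny, nz)))
    inserts[[i]] <- idx3
    arr[idx3] <- densities[i]
  }
  grey <- (arr - grey_intercept) / grey_slope
  set.seed(seed)
  if (noise_sd > 0) grey <- grey + stats::rnorm(length(grey), 0, noise_sd)
  list(image = voxel_image(array(grey, dim(arr)), spacing = 10.4, "grey"),
       truth = list(insert_voxels = inserts, densities = densities,
                    grey_slope = grey_slope, grey_intercept = grey_intercept))
}
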