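test_that("digital sphere local thickness matches its diameter", {
  m <- digital_sphere(21)
  th <- local_thickness(bone_mask(m, 1))
  mt <- mean(th$data[m == 1])
  expect_gte(mt, 20)
  expect_lte(mt, 22)
  expect_true(all(th$data[m == 0] == 0))
})

test_that("interior plate thickness is exactly its slice count", {
  p <- array(0L, c(30, 30, 21))
  p[, , 6:16] <- 1L # 11-slice plate
  th <- local_thickness(bone_mask(p, 1))
  # away from the lateral borders every plate voxel sees exactly 11 voxels
  interior <- th$data[8:23, 8:23, 6:16]
  expect_true(all(interior == 11))
})

test_that("local thickness equals the exhaustive-sphere oracle", {
  for (seed in 1:3) {
    m <- random_blob_mask(16, seed)
    if (sum(m) == 0) next
    th <- local_thickness(bone_mask(m, 1))$data
    ref <- local_thickness_oracle(m)
    expect_equal(th, ref, tolerance = 0)
  }
  # and on a structured case: two fused spheres
  m <- digital_sphere(9, 24)
  m2 <- digital_sphere(13, 24)
  shifted <- array(0L, dim(m))
  shifted[7:24, , ] <- m2[1:18, , ]
  fused <- pmax(m, shifted)
  expect_equal(local_thickness(bone_mask(fused, 1))$data,
               local_thickness_oracle(fused), tolerance = 0)
})

test_that("thickness scales linearly with voxel spacing", {
  m <- digital_sphere(9)
  t1 <- local_thickness(bone_mask(m, 1))$data
  t10 <- local_thickness(bone_mask(m, 10.4))$data
  expect_equal(t10, t1 * 10.4, tolerance = 1e-12)
})

test_that("BV/TV is exact voxel counting", {
  set.seed(8)
  total <- array(1L, c(12, 12, 12))
  phase <- array(rbinom(12^3, 1, 0.3), c(12, 12, 12))
  expect_equal(bvtv(phase, total), 100 * sum(phase) / 12^3)
  expect_error(bvtv(total, phase), "subset")
  expect_error(bvtv(phase * 0L, total * 0L), "empty")
})

test_that("Tb.N is the plate-model ratio with guarded edge cases", {
  expect_equal(tb_n(10, 50), (10 / 100) / (50 / 1000))
  expect_equal(tb_n(0, 50), 0)
  expect_error(tb_n(10, 0), "positive")
})

test_that("trabecular VOI strips the cortex and keeps every rod", {
  s <- phantom_spec(dim = c(108L, 108L, 160L),
                    outer_radius_profile = data.frame(
                      z_mm = c(0, 0.8, 1.1, 1.7),
                      radius_um = c(480, 460, 380, 340)),
                    cortical_thickness_profile = data.frame(
                      z_mm = c(0, 0.8, 1.1, 1.7),
                      thickness_um = c(80, 80, 230, 200)),
                    trabecular_zrange_mm = c(0.1, 0.75),
                    noise_sd = 0, seed = 21)
  ph <- generate_tibia_phantom(s)
  mask <- segment(ph$left, s$tissue_density / s$grey_slope / 2)
  voi <- extract_trabecular_voi(mask, ref_slice = 10, offset_mm = 0.1,
                                height_mm = 0.4)
  lab <- ph$truth$left$labels[, , voi$slices]
  # no cortical voxel survives in the trabecular bone phase
  expect_equal(sum(voi$bone$data[lab == 1]), 0L)
  # every rod present in the slab is recovered as its own 6-connected blob
  labcc <- tibiamct:::cc_label_cpp(voi$bone$data, dim(voi$bone$data), 6L)
  expect_equal(max(labcc), ph$truth$left$rod_count)
  # and the bone phase is exactly the rod phase
  expect_equal(sum(voi$bone$data != 0), sum(lab == 2))
  # measured BV/TV matches exact counting within the analytic region
  tm <- trabecular_metrics(voi)
  expect_equal(tm[["Tb.BV/TV"]], bvtv(voi$bone, voi$region))
  expect_equal(tm[["Tb.N"]], tb_n(tm[["Tb.BV/TV"]], tm[["Tb.Th"]]))
})

test_that("cortical metrics recover an analytic annulus", {
  # ideal annulus: outer radius 30 px, wall 8 px, 10 slices, 20 um voxels
  n <- 72
  a <- array(0L, c(n, n, 10))
  co <- as.matrix(expand.grid(1:n, 1:n))
  rho <- sqrt((co[, 1] - (n + 1) / 2)^2 + (co[, 2] - (n + 1) / 2)^2)
  sl <- matrix(0L, n, n)
  sl[co[rho <= 30 & rho > 22, , drop = FALSE]] <- 1L
  for (k in 1:10) a[, , k] <- sl
  mask <- bone_mask(a, 20)
  cm <- cortical_metrics(mask, height_mm = 0.2, closing_radius = 5L)
  sp_mm <- 0.02
  tt_exact <- sum(rho <= 30) * sp_mm^2
  ct_exact <- sum(rho <= 30 & rho > 22) * sp_mm^2
  expect_equal(cm[["Tt.Ar"]], tt_exact, tolerance = 1e-10)
  # pore closing rounds digital corners slightly, so Ct.Ar is near-exact
  expect_equal(cm[["Ct.Ar"]], ct_exact, tolerance = 0.02)
  expect_equal(cm[["Ct.Ar/Tt.Ar"]], 100 * ct_exact / tt_exact,
               tolerance = 0.02)
  # wall is 8 px = 160 um; the slab is 10 voxels high, so the 3D thickness
  # is limited by the wall, not the slab height
  expect_gt(cm[["Ct.Th"]], 120)
  expect_lt(cm[["Ct.Th"]], 180)
})

test_that("pore closing restores the areas of a porous annulus", {
  n <- 72
  a <- array(0L, c(n, n, 10))
  co <- as.matrix(expand.grid(1:n, 1:n))
  rho <- sqrt((co[, 1] - (n + 1) / 2)^2 + (co[, 2] - (n + 1) / 2)^2)
  sl <- matrix(0L, n, n)
  sl[co[rho <= 30 & rho > 22, , drop = FALSE]] <- 1L
  slp <- sl
  slp[34:38, 8:10] <- 0L # intracortical pore
  for (k in 1:10) a[, , k] <- slp
  cm_porous <- cortical_metrics(bone_mask(a, 20), height_mm = 0.2,
                                closing_radius = 5L)
  b <- array(0L, c(n, n, 10)); for (k in 1:10) b[, , k] <- sl
  cm_solid <- cortical_metrics(bone_mask(b, 20), height_mm = 0.2,
                               closing_radius = 5L)
  expect_equal(cm_porous[["Ct.Ar"]], cm_solid[["Ct.Ar"]], tolerance = 1e-10)
})

test_that("an open arc cross-section raises a warning", {
  n <- 72
  a <- array(0L, c(n, n, 6))
  co <- as.matrix(expand.grid(1:n, 1:n))
  rho <- sqrt((co[, 1] - (n + 1) / 2)^2 + (co[, 2] - (n + 1) / 2)^2)
  ang <- atan2(co[, 2] - (n + 1) / 2, co[, 1] - (n + 1) / 2)
  sl <- matrix(0L, n, n)
  sel <- rho <= 30 & rho > 26 & abs(ang) < 2 # thin arc, large gap
  sl[co[sel, , drop = FALSE]] <- 1L
  for (k in 1:6) a[, , k] <- sl
  expect_warning(cortical_metrics(bone_mask(a, 20), height_mm = 0.12,
                                  closing_radius = 2L),
                 "open")
})

test_that("VOI bounds are validated", {
  a <- array(1L, c(10, 10, 20))
  expect_error(extract_trabecular_voi(bone_mask(a, 100), ref_slice = 15,
                                      offset_mm = 0.2, height_mm = 1),
               "exceeds")
})
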