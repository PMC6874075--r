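#' Analysis configuration
#'
#' Bundles the preprocessing, VOI, calibration, FE and output options used
#' by [run_specimen()] and [run_study()].
#'
#' @param sigma Gaussian filter SD, voxels.
#' @param despeckle_min minimum surviving 3D component size, voxels.
#' @param threshold `"auto"` (histogram bimodal midpoint) or a numeric grey
#'   level.
#' @param grey_slope,grey_intercept densitometric calibration
#'   (`TMD = intercept + slope * grey`).
#' @param ref_slice reference slice for the trabecular and densitometric
#'   VOIs; `NULL` takes it from phantom ground truth.
#' @param trab_offset_mm,trab_height_mm trabecular VOI placement.
#' @param cort_height_mm cortical VOI height at the midshaft.
#' @param densito_fraction fraction of tibia length in the densitometric VOI.
#' @param do_fe run the micro-FE stiffness/strength solves on the midshaft
#'   cortical VOI (off by default: it dominates runtime).
#' @param fe_spec an [fe_model_spec()].
#' @param out_dir optional output directory for CSV results.
#' @param seed integer seed recorded in outputs.
#' @return A list of class `run_config`.
#' @export
run_config <- function(sigma = 0.65, despeckle_min = 10L, threshold = "auto",
                       grey_slope = 0.5, grey_intercept = 0,
                       ref_slice = NULL, trab_offset_mm = 0.2,
                       trab_height_mm = 1.0, cort_height_mm = 1.0,
                       densito_fraction = 0.8, do_fe = FALSE,
                       fe_spec = fe_model_spec(), out_dir = NULL,
                       seed = 1L) {
  structure(list(sigma = sigma, despeckle_min = despeckle_min,
                 threshold = threshold, grey_slope = grey_slope,
                 grey_intercept = grey_intercept, ref_slice = ref_slice,
                 trab_offset_mm = trab_offset_mm,
                 trab_height_mm = trab_height_mm,
                 cort_height_mm = cort_height_mm,
                 densito_fraction = densito_fraction, do_fe = do_fe,
                 fe_spec = fe_spec, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  flat <- utils::capture.output(utils::str(config, digits.d = 12))
  substr(paste(format(sum(utf8ToInt(paste(flat, collapse = "")) *
                            seq_along(utf8ToInt(paste(flat, collapse = ""))) %%
                            2147483647)), collapse = ""), 1, 12)
}

#' Analyse one specimen image
#'
#' Runs the full per-bone chain: Gaussian filter, global threshold (auto or
#' supplied), segmentation, despeckling, tibia length, trabecular and
#' cortical morphometry, calibration to TMD, densitometric VOI with 40
#' partitions and total BMC, and optionally the micro-FE stiffness and
#' strength solves on the midshaft VOI.
#'
#' @param image a grey-valued [voxel_image()].
#' @param config a [run_config()].
#' @param ref_slice reference slice (overrides the config, e.g. from phantom
#'   ground truth).
#' @param mirror mirror the image across the sagittal plane before analysis
#'   (the horizontal flip applied so both limbs share one anatomical frame).
#' @return A list of class `specimen_result`: `metrics` (one-row data.frame
#'   with Tb.BV/TV, Tb.Th, Tb.Sp, Tb.N, Tt.Ar, Ct.Ar, Ct.Ar/Tt.Ar, Ct.Th,
#'   Length, Tot.BMC), `partitions` (40-row table), `threshold`, `fe`
#'   (optional), `mask`.
#' @export
run_specimen <- function(image, config = run_config(), ref_slice = NULL,
                         mirror = FALSE) {
  stopifnot(inherits(image, "voxel_image"))
  if (is.null(ref_slice)) ref_slice <- config$ref_slice
  if (is.null(ref_slice)) stop("a reference slice is required")
  if (mirror) {
    image <- voxel_image(flip_x(image$data), image$spacing, image$value_kind)
  }
  filt <- gaussian_filter(image, config$sigma)
  thr <- if (identical(config$threshold, "auto"))
    as.numeric(compute_threshold(filt)) else config$threshold
  mask <- despeckle(segment(filt, thr), min_size = config$despeckle_min)
  len <- tibia_length(mask)
  tvoi <- extract_trabecular_voi(mask, ref_slice,
                                 offset_mm = config$trab_offset_mm,
                                 height_mm = config$trab_height_mm)
  tm <- trabecular_metrics(tvoi)
  cm <- cortical_metrics(mask, height_mm = config$cort_height_mm)
  curve <- structure(list(slope = config$grey_slope,
                          intercept = config$grey_intercept,
                          residuals = 0, source_densities = numeric(0)),
                     class = "calibration_curve")
  tmd <- to_tmd(filt, curve)
  dvoi <- densitometric_voi(mask, start_slice = ref_slice,
                            fraction = config$densito_fraction)
  grid <- partition_voi(dvoi)
  ptab <- partition_metrics(tmd, dvoi, grid)
  bmc <- total_bmc(tmd, dvoi)
  fe <- NULL
  if (isTRUE(config$do_fe)) {
    m <- as_mask_array(mask)
    zs <- which(apply(m, 3, function(sl) any(sl != 0)))
    mid <- round((min(zs) + max(zs)) / 2)
    half <- round(config$cort_height_mm / (mask$spacing / 1000) / 2)
    sub <- bone_mask(m[, , (mid - half):(mid + half - 1), drop = FALSE],
                     mask$spacing)
    mesh <- build_mesh(sub)
    fe <- list(stiffness = solve_stiffness(mesh, config$fe_spec),
               strength = solve_strength(mesh, config$fe_spec))
  }
  metrics <- cbind(tm, cm,
                   data.frame(Length = len, Tot.BMC = bmc,
                              check.names = FALSE))
  if (!is.null(fe)) {
    metrics$Stiffness <- fe$stiffness$stiffness
    metrics$Strength <- fe$strength$strength
  }
  structure(list(metrics = metrics, partitions = ptab, threshold = thr,
                 fe = fe, mask = mask, ref_slice = ref_slice,
                 config = config),
            class = "specimen_result")
}

#' Run a paired phantom study end to end
#'
#' Generates one phantom pair per mouse (with seeded between-mouse geometry
#' variation), analyses both limbs, pools the study records and estimates
#' the Radiation&Side effect per parameter with the full mixed-model
#' contract (fit, assumption checks, interaction pruning, marginal-mean
#' contrast). Per-partition paired differences are summarised as
#' median +- SD across mice.
#'
#' @param cohort data.frame with columns `mouse`, `strain`, `intervention`.
#' @param base_spec a [phantom_spec()]; its `effect` is applied to every
#'   right limb.
#' @param config a [run_config()].
#' @param parameters parameters to model (default the trabecular set plus
#'   total area).
#' @param mouse_cv geometric coefficient of variation between mice applied
#'   to the rod spacing and outer radius (gives the random mouse effect).
#' @return A list of class `study_result`: `records`, `effects` (named list
#'   of `effect_estimate`), `assumptions`, `partition_summary`,
#'   `specimens`, `seed`.
#' @export
run_study <- function(cohort, base_spec = phantom_spec(),
                      config = run_config(),
                      parameters = c("Tb.BV/TV", "Tb.Th", "Tb.Sp", "Tb.N",
                                     "Tt.Ar"),
                      mouse_cv = 0.05) {
  need <- c("mouse", "strain", "intervention")
  if (!all(need %in% names(cohort)) || nrow(cohort) == 0)
    stop("cohort must be a non-empty data.frame with mouse, strain, intervention")
  set.seed(config$seed)
  mouse_seeds <- sample.int(2^31 - 2, nrow(cohort))
  mouse_jit <- matrix(stats::runif(2 * nrow(cohort), 1 - mouse_cv,
                                   1 + mouse_cv), ncol = 2)
  rows <- list()
  pdiffs <- list()
  specimens <- list()
  failures <- character(0)
  for (i in seq_len(nrow(cohort))) {
    spec_i <- base_spec
    spec_i$seed <- mouse_seeds[i]
    spec_i$rod_spacing <- base_spec$rod_spacing * mouse_jit[i, 1]
    spec_i$outer_radius_profile$radius_um <-
      base_spec$outer_radius_profile$radius_um * mouse_jit[i, 2]
    res <- tryCatch({
      ph <- generate_tibia_phantom(spec_i)
      L <- run_specimen(ph$left, config, ref_slice = spec_i$ref_slice)
      R <- run_specimen(ph$right, config, ref_slice = spec_i$ref_slice,
                        mirror = TRUE)
      list(L = L, R = R)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", cohort$mouse[i],
                                      conditionMessage(res)))
      next
    }
    specimens[[as.character(cohort$mouse[i])]] <- res
    for (side in c("L", "R")) {
      met <- res[[side]]$metrics
      rows[[length(rows) + 1]] <- data.frame(
        mouse = cohort$mouse[i], strain = cohort$strain[i],
        intervention = cohort$intervention[i], side = side,
        parameter = names(met), value = as.numeric(met[1, ]),
        stringsAsFactors = FALSE)
    }
    pdiffs[[length(pdiffs) + 1]] <-
      paired_partition_difference(res$L$partitions, res$R$partitions)
  }
  if (!length(rows)) stop("all specimens failed: ",
                          paste(failures, collapse = "; "))
  records <- study_records(do.call(rbind, rows))
  effects <- list()
  assumptions <- list()
  for (p in intersect(parameters, unique(records$parameter))) {
    fit <- fit_radiation_model(records, p)
    assumptions[[p]] <- check_assumptions(records, p, model = fit)
    effects[[p]] <- radiation_contrast(prune_interactions(fit))
  }
  out <- structure(list(records = records, effects = effects,
                        assumptions = assumptions,
                        partition_summary = partition_cohort_summary(pdiffs),
                        partition_diffs = pdiffs,
                        specimens = specimens, failures = failures,
                        seed = config$seed),
                   class = "study_result")
  if (!is.null(config$out_dir)) write_study(out, config)
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d mice analysed, %d failures, seed %d\n",
              length(x$specimens), length(x$failures), x$seed))
  for (p in names(x$effects)) {
    e <- x$effects[[p]]
    cat(sprintf("  %-10s diff %% of left mean: %6.1f (%.1f, %.1f)\n",
                p, e$percent_diff, e$percent_ci[1], e$percent_ci[2]))
  }
  invisible(x)
}

# CSV outputs with provenance headers (config hash + seed)
write_study <- function(study, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- sprintf("# tibiamct config %s seed %d", config_hash(config),
                 config$seed)
  wcsv <- function(df, name) {
    path <- file.path(config$out_dir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  wcsv(study$records, "records.csv")
  eff <- do.call(rbind, lapply(study$effects, function(e)
    data.frame(parameter = e$parameter, mean_L = e$mean_L, mean_R = e$mean_R,
               diff = e$diff, ci_low = e$ci[1], ci_high = e$ci[2],
               sd = e$sd_paired,
               pct_diff = round(e$percent_diff, 1),
               pct_low = round(e$percent_ci[1], 1),
               pct_high = round(e$percent_ci[2], 1),
               p_value = e$p_value)))
  wcsv(eff, "effects.csv")
  wcsv(study$partition_summary, "partition_summary.csv")
  invisible(config$out_dir)
}
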