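test_that("study record validation coerces and rejects malformed tables", {
  rec <- simulate_study_records(n_per_group = 3, seed = 1)
  expect_s3_class(rec, "data.frame")
  expect_true(is.factor(rec$side))
  expect_identical(levels(rec$side), c("L", "R"))
  bad <- rec
  bad$side <- as.character(bad$side)
  bad$side[1] <- "X"
  expect_error(study_records(bad), "'L' or 'R'")
  expect_error(study_records(rec[, -6]), "missing columns")
  dup <- rbind(rec, rec[1, ])
  expect_error(study_records(dup), "more than one record")
})

test_that("percent difference reproduces the published reporting convention", {
  # marginal mean of the control limb and the R - L difference, as printed
  expect_equal(round(percent_difference(1.765, 53.7), 1), 3.3)
  expect_equal(round(percent_difference(-0.203, 1.43), 1), -14.2)
  expect_equal(round(percent_difference(-0.955, 6.40), 1), -14.9)
  expect_equal(round(percent_difference(-0.046, 0.917), 1), -5.0)
  # the separation entry is reproducible only to within a tenth of a point
  # because the printed mean has 3 significant figures
  expect_lt(abs(percent_difference(41.737, 358) - 11.6), 0.1)
  expect_error(percent_difference(1, 0), "nonzero")
})

test_that("the mixed model recovers a known injected paired effect", {
  rec <- simulate_study_records(n_per_group = 10, delta_pct = -14.2,
                                seed = 3)
  fit <- fit_radiation_model(rec, "Tb.N")
  expect_s3_class(fit, "radiation_model")
  expect_true(all(c("strain", "intervention", "side",
                    "strain:intervention") %in% names(fit$p_values)))
  eff <- radiation_contrast(prune_interactions(fit))
  expect_s3_class(eff, "effect_estimate")
  expect_lt(eff$percent_ci[1], -14.2)
  expect_gt(eff$percent_ci[2], -14.2)
  expect_lt(eff$p_value, 0.001)
  # percent scaling is consistent with the raw difference
  expect_equal(eff$percent_diff, 100 * eff$diff / eff$mean_L)
})

test_that("a paired model collapses to the mean within-mouse difference", {
  # with side as the only fixed effect the marginal contrast R - L equals
  # the arithmetic mean of the paired differences
  set.seed(4)
  rec <- simulate_study_records(n_per_group = 6, delta_pct = -10, seed = 4)
  fit <- fit_radiation_model(rec, "Tb.N")
  pruned <- prune_interactions(fit, alpha = 1e-9) # drop all interactions
  eff <- radiation_contrast(pruned)
  wide <- stats::reshape(pruned$data[, c("mouse", "side", "value")],
                         idvar = "mouse", timevar = "side",
                         direction = "wide")
  expect_equal(eff$diff, mean(wide$value.R - wide$value.L),
               tolerance = 1e-8)
  expect_equal(eff$sd_paired, stats::sd(wide$value.R - wide$value.L))
})

test_that("interaction pruning removes noise terms and keeps main effects", {
  rec <- simulate_study_records(n_per_group = 10, delta_pct = -14.2,
                                seed = 5)
  fit <- fit_radiation_model(rec, "Tb.N")
  pr <- prune_interactions(fit)
  expect_true(pr$pruned)
  kept <- names(pr$p_values)
  expect_true(all(c("strain", "intervention", "side") %in% kept))
  inter <- grep(":", kept, value = TRUE)
  if (length(inter)) expect_true(all(pr$p_values[inter] < 0.05))
  # with a strong simulated interaction the term is retained
  rec2 <- simulate_study_records(n_per_group = 10, seed = 6)
  rec2$value <- rec2$value +
    ifelse(rec2$strain == "B6" & rec2$side == "R", -1.5, 0)
  fit2 <- prune_interactions(fit_radiation_model(rec2, "Tb.N"))
  expect_true("strain:side" %in% names(fit2$p_values))
})

test_that("assumption checks flag heteroscedastic groups and pick the worse", {
  rec <- simulate_study_records(n_per_group = 12, seed = 7)
  # inflate variance in one intervention group only
  set.seed(7)
  ovx <- rec$intervention == "OVX"
  rec$value[ovx] <- mean(rec$value[ovx]) +
    (rec$value[ovx] - mean(rec$value[ovx])) * 6
  chk <- check_assumptions(rec, "Tb.N")
  expect_lt(chk$levene_intervention_p, 0.05)
  expect_true(chk$split_recommended)
  expect_identical(chk$split_factor, "intervention")
  # homogeneous data: no split recommended (checked over several seeds to
  # avoid relying on one realisation)
  flags <- vapply(11:14, function(s) {
    r <- simulate_study_records(n_per_group = 12, seed = s)
    check_assumptions(r, "Tb.N")$split_recommended
  }, logical(1))
  expect_lt(mean(flags), 0.5)
})

test_that("residual normality test behaves on normal and skewed data", {
  rec <- simulate_study_records(n_per_group = 12, seed = 8)
  chk <- check_assumptions(rec, "Tb.N")
  expect_gt(chk$shapiro_p, 0.001)
  set.seed(8)
  rec$value <- rec$value + rexp(nrow(rec), 2)^3
  chk2 <- check_assumptions(rec, "Tb.N")
  expect_lt(chk2$shapiro_p, chk$shapiro_p)
})

test_that("single-level factors trigger the reduced-model fallback", {
  rec <- simulate_study_records(n_per_group = 6, seed = 9)
  sub <- rec[rec$strain == "B6", ]
  expect_warning(fit <- fit_radiation_model(sub, "Tb.N"), "reduced model")
  expect_false("strain" %in% names(fit$p_values))
  eff <- radiation_contrast(prune_interactions(fit))
  expect_true(is.finite(eff$percent_diff))
})

test_that("modelling fails loudly without enough paired mice", {
  rec <- simulate_study_records(n_per_group = 1, seed = 10)
  rec <- rec[rec$mouse %in% unique(rec$mouse)[1:2], ]
  expect_error(fit_radiation_model(rec, "Tb.N"), "3 mice")
  expect_error(fit_radiation_model(rec, "nope"), "no records")
})

test_that("null-effect rejection rate is near the nominal level", {
  # moderate replicate count here; the acceptance suite runs the full check
  reps <- 60
  rej <- 0
  for (s in seq_len(reps)) {
    rec <- simulate_study_records(n_per_group = 10, delta_pct = 0,
                                  seed = 20000 + s)
    fit <- prune_interactions(fit_radiation_model(rec, "Tb.N"))
    if (fit$p_values[["side"]] < 0.05) rej <- rej + 1
  }
  expect_lte(rej / reps, 0.15)
})

test_that("simulated records honour their generating parameters", {
  rec <- simulate_study_records(n_per_group = 50, delta_pct = -20, mu = 2,
                                sd_mouse = 0.01, sd_resid = 0.01, seed = 11)
  wide <- stats::reshape(rec[, c("mouse", "side", "value")], idvar = "mouse",
                         timevar = "side", direction = "wide")
  expect_equal(mean(wide$value.R - wide$value.L), -0.2 * 2,
               tolerance = 0.01)
  expect_equal(nrow(rec), 50 * 4 * 2)
  expect_equal(length(unique(rec$mouse)), 200)
})

test_that("print methods summarise the fit and the effect", {
  rec <- simulate_study_records(n_per_group = 5, seed = 12)
  fit <- fit_radiation_model(rec, "Tb.N")
  expect_output(print(fit), "radiation_model")
  eff <- radiation_contrast(prune_interactions(fit))
  expect_output(print(eff), "diff % of left mean")
  s <- summary(fit)
  expect_true("side1" %in% rownames(s$coefficients))
})
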