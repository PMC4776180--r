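# The recording-analysis pipeline and its synthetic data generator.

test_that("preferred-stimulus classification recovers tuning peaks", {
  tab <- tiny_recording()
  prefs <- classify_preferred_stimulus(tab)
  expect_equal(prefs$preferred, 1:11)
  # monotone neuron prefers the last stimulus
  mono <- tab[tab$neuron_id == 1, ]
  mono$rate <- mono$stimulus / 11
  expect_equal(classify_preferred_stimulus(mono)$preferred, 11L)
  # permuting stimulus labels permutes preferences
  perm <- sample(11)
  tab2 <- tab; tab2$stimulus <- perm[tab2$stimulus]
  prefs2 <- classify_preferred_stimulus(tab2)
  expect_equal(prefs2$preferred, perm[prefs$preferred])
  # missing stimulus raises an informative error
  gap <- tab[!(tab$neuron_id == 3 & tab$stimulus == 5), ]
  expect_error(classify_preferred_stimulus(gap), "missing stimuli.*3")
})

test_that("generator ground truth is recovered by classification", {
  set.seed(81)
  gen <- generate_synthetic_recording()
  expect_equal(length(unique(gen$table$neuron_id)), 125L)
  expect_equal(sort(unique(gen$table$stimulus)), 1:11)
  expect_equal(sort(unique(gen$table$task)),
               c("categorization", "discrimination", "fixation"))
  expect_equal(length(gen$truth$preferred), 125L)
  expect_true(all(table(gen$truth$preferred) >= 11))
  prefs <- classify_preferred_stimulus(gen$table)
  expect_gte(mean(prefs$preferred == gen$truth$preferred), 0.95)
})

test_that("normalisation pins the fixation maximum at one", {
  tab <- tiny_recording(gain = c(fixation = 2, categorization = 2.4,
                                 discrimination = 2))
  norm <- normalize_rates(tab)
  fix_max <- tapply(norm$rate[norm$task == "fixation"],
                    norm$neuron_id[norm$task == "fixation"], max)
  expect_equal(as.numeric(fix_max), rep(1, 11))
  # a neuron 1.2x above fixation keeps ratio 1.2 after normalisation
  cat_max <- tapply(norm$rate[norm$task == "categorization"],
                    norm$neuron_id[norm$task == "categorization"], max)
  expect_equal(as.numeric(cat_max), rep(1.2, 11))
  # zero fixation maximum: neuron dropped with a warning
  dead <- tab
  dead$rate[dead$neuron_id == 4 & dead$task == "fixation"] <- 0
  expect_warning(norm2 <- normalize_rates(dead), "zero fixation")
  expect_false(4 %in% norm2$neuron_id)
})

test_that("population profiles average within preference groups", {
  tab <- tiny_recording()
  prefs <- classify_preferred_stimulus(tab)
  prof <- population_profile(tab, "fixation", 6, 100, prefs)
  # one neuron per group with exact Gaussian tuning: the profile is the
  # tuning curve around stimulus 6
  expect_equal(prof, exp(-((1:11) - 6)^2 / (2 * 1.8^2)), tolerance = 1e-12)
  # invariant to neuron (row) order
  shuffled <- tab[sample(nrow(tab)), ]
  expect_equal(population_profile(shuffled, "fixation", 6, 100, prefs),
               prof)
})

test_that("Gaussian profile fits recover parameters and flag degeneracy", {
  x <- 1:11
  y <- 1 * exp(-(x - 6)^2 / (2 * 2^2))
  fit <- fit_gaussian_profile(y)
  expect_equal(fit$peak_locus, 6, tolerance = 1e-6)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$width, 2, tolerance = 1e-6)
  expect_true(fit$reliable)
  # noisy recovery over replicates
  set.seed(91)
  mus <- replicate(100, {
    fit_gaussian_profile(y + rnorm(11, 0, 0.05))$peak_locus
  })
  expect_lt(abs(mean(mus) - 6), 0.1)
  # flat profile: no spurious peak
  flat <- fit_gaussian_profile(rep(0.5, 11))
  expect_false(flat$converged)
  expect_false(flat$reliable)
  expect_error(fit_gaussian_profile(c(1, 2, NA, NA, NA, NA, NA, NA, NA,
                                      3, 2)), ">= 5")
})

test_that("same-task peak-shift differences are zero and flagged", {
  set.seed(101)
  gen <- generate_synthetic_recording(synth_ground_truth(noise_sd = 0))
  curve <- peak_shift_dynamics(gen$table, "discrimination",
                               "discrimination")
  expect_true(all(abs(curve$curve$shift_raw) < 1e-9))
  expect_true(all(!curve$curve$normalized))  # floored, reported raw
})

test_that("injected peak-shift dynamics are recovered with correct signs", {
  set.seed(102)
  truth <- synth_ground_truth()
  gen <- generate_synthetic_recording(truth)
  curve <- peak_shift_dynamics(gen$table)
  cc <- curve$curve
  # raw shifts match the injected displacement in magnitude and sign
  injected <- ifelse(cc$stimulus < truth$boundary, -1, 1) *
    truth$delta[as.character(cc$time_bin_ms)]
  expect_lt(stats::median(abs(cc$shift_raw - injected)), 0.15)
  # normalised curves grow with time
  growth <- tapply(abs(cc$shift), cc$time_bin_ms, mean, na.rm = TRUE)
  expect_gt(cor(as.numeric(names(growth)), growth, method = "spearman"),
            0.8)
  bc <- boundary_consistency(curve)
  late <- bc$window_mean
  expect_true(all(late$mean_shift[late$stimulus %in% 2:4] < 0))
  expect_true(all(late$mean_shift[late$stimulus %in% 8:10] > 0))
  expect_gt(bc$crossing, 5); expect_lt(bc$crossing, 6)
})

test_that("boundary inference interpolates the sign change", {
  # synthetic curve object via the real pipeline on a boundary-6 generator
  set.seed(103)
  gen <- generate_synthetic_recording(synth_ground_truth(boundary = 6))
  bc <- boundary_consistency(peak_shift_dynamics(gen$table))
  expect_lt(abs(bc$crossing - 6), 0.25)
  # all-positive curves have no crossing
  set.seed(104)
  gen2 <- generate_synthetic_recording(synth_ground_truth(boundary = 1.5))
  bc2 <- boundary_consistency(peak_shift_dynamics(gen2$table))
  expect_true(all(bc2$window_mean$mean_shift > 0))
  expect_true(is.na(bc2$crossing))
})

test_that("bootstrap SDs are zero on noiseless data and deterministic", {
  set.seed(105)
  gen <- generate_synthetic_recording(synth_ground_truth(noise_sd = 0),
                                      n_neurons = 33L)
  sds <- bootstrap_peak_sd(gen$table, n_resamples = 5)
  expect_lt(max(sds$sd_raw, na.rm = TRUE), 1e-6)
  set.seed(1); a <- bootstrap_peak_sd(gen$table, n_resamples = 3)
  set.seed(1); b <- bootstrap_peak_sd(gen$table, n_resamples = 3)
  expect_identical(a, b)
})

test_that("null data stay within bootstrap error bars", {
  set.seed(106)
  null <- generate_synthetic_recording(synth_ground_truth(
    shift_max = 0,
    task_gain = c(fixation = 1, categorization = 1, discrimination = 1)))
  curve <- peak_shift_dynamics(null$table)
  sds <- bootstrap_peak_sd(null$table, n_resamples = 30)
  merged <- merge(curve$curve, sds, by = c("stimulus", "time_bin_ms"))
  frac <- mean(abs(merged$shift_raw) > 2 * merged$sd_raw, na.rm = TRUE)
  expect_lte(frac, 0.10)
})
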