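# Population-recording analysis pipeline: preferred-stimulus grouping,
# fixation-max normalisation, Gaussian fits of the 11-point population
# activity profile per time bin, task-difference peak-shift dynamics with a
# neuron-level bootstrap, and a synthetic multi-task recording generator
# with known ground truth.
#
# A recording table is a tidy data.frame with columns
#   neuron_id, task ("fixation" | "categorization" | "discrimination"),
#   stimulus (1..11), time_bin_ms (bin centre), rate (trial-averaged, >= 0).

RECORDING_COLS <- c("neuron_id", "task", "stimulus", "time_bin_ms", "rate")

check_recording_table <- function(table) {
  if (!is.data.frame(table) || !all(RECORDING_COLS %in% names(table)))
    stop("recording table must have columns ",
         paste(RECORDING_COLS, collapse = ", "), call. = FALSE)
  if (any(!is.finite(table$rate)))
    stop("rates must be finite", call. = FALSE)
  invisible(table)
}

#' Ground truth for the synthetic recording generator
#'
#' Defines what the generator injects: per-task gain, the time-growing
#' tuning-peak displacement `delta(t)` (in stimulus-index units) applied in
#' the shifted tasks, the category-boundary position that sets its polarity
#' (stimuli below the boundary shift toward index 1/"red", above toward
#' index 11/"green"), and the additive noise SD.
#'
#' @param task_gain named gains for the three tasks; categorization exceeds
#'   discrimination by default, as observed in IT.
#' @param shift_max displacement at the last time bin (index units);
#'   `delta(t) = shift_max * t / max(time_bins)`, so the value at the
#'   100 ms normalisation bin is positive.
#' @param boundary category-boundary position on the 1..11 stimulus axis.
#' @param shift_tasks tasks in which the displacement is applied; by
#'   default only categorization, so the fixation task stays neutral as the
#'   reference that anchors classification and normalisation.
#' @param tuning_sd SD of the bell-shaped tuning over stimulus index.
#' @param noise_sd additive rate noise SD (normalised rate units).
#' @param time_bins bin centres in ms (50-ms bins spanning 100-550 ms by
#'   default).
#' @return an object of class `synth_ground_truth`.
#' @export
synth_ground_truth <- function(task_gain = c(fixation = 1,
                                             categorization = 1.2,
                                             discrimination = 1),
                               shift_max = 0.6, boundary = 5.5,
                               shift_tasks = "categorization",
                               tuning_sd = 1.8, noise_sd = 0.1,
                               time_bins = seq(100, 550, by = 50)) {
  stopifnot(all(c("fixation", "categorization", "discrimination") %in%
                  names(task_gain)),
            shift_max >= 0, tuning_sd > 0, noise_sd >= 0,
            boundary > 1, boundary < 11, length(time_bins) >= 2)
  delta <- shift_max * time_bins / max(time_bins)
  structure(list(task_gain = task_gain, shift_max = shift_max,
                 boundary = boundary, shift_tasks = shift_tasks,
                 tuning_sd = tuning_sd, noise_sd = noise_sd,
                 time_bins = time_bins,
                 delta = stats::setNames(delta, time_bins),
                 delta_at_100 = delta[match(100, time_bins)]),
            class = "synth_ground_truth")
}

#' Generate a synthetic multi-task recording table
#'
#' Emulates a population of colour-selective IT neurons recorded in three
#' tasks with 11 sample stimuli on a red-to-green line: each neuron gets a
#' preferred stimulus (balanced over 1..11), a bell-shaped tuning curve over
#' stimulus index, a task-dependent gain, and -- in the shifted tasks -- an
#' effective stimulus displaced by `delta(t)` away from the category
#' boundary (reddish stimuli toward red, greenish toward green).  Additive
#' Gaussian rate noise is rectified at zero.
#'
#' @param truth a [synth_ground_truth()].
#' @param n_neurons number of neurons (125 by default).
#' @param n_stimuli number of sample stimuli (must be 11 for the standard
#'   pipeline).
#' @param tasks tasks to generate.
#' @return a list with `table` (the tidy recording table) and `truth` (the
#'   input truth augmented with the per-neuron `preferred` assignment).
#' @export
generate_synthetic_recording <- function(truth = synth_ground_truth(),
                                         n_neurons = 125L,
                                         n_stimuli = 11L,
                                         tasks = c("fixation",
                                                   "categorization",
                                                   "discrimination")) {
  stopifnot(inherits(truth, "synth_ground_truth"))
  check_scalar(n_neurons, "n_neurons", lower = n_stimuli, integer = TRUE)
  check_scalar(n_stimuli, "n_stimuli", lower = 3, integer = TRUE)
  stopifnot(all(tasks %in% names(truth$task_gain)))
  preferred <- sort(rep_len(seq_len(n_stimuli), n_neurons))
  grid <- expand.grid(neuron_id = seq_len(n_neurons), task = tasks,
                      stimulus = seq_len(n_stimuli),
                      time_bin_ms = truth$time_bins,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  pref <- preferred[grid$neuron_id]
  dir <- sign(grid$stimulus - truth$boundary)  # +1 greenish, -1 reddish
  shift_on <- grid$task %in% truth$shift_tasks
  s_eff <- grid$stimulus +
    ifelse(shift_on, dir * truth$delta[as.character(grid$time_bin_ms)], 0)
  rate <- truth$task_gain[grid$task] *
    exp(-(pref - s_eff)^2 / (2 * truth$tuning_sd^2))
  if (truth$noise_sd > 0)
    rate <- rate + stats::rnorm(length(rate), 0, truth$noise_sd)
  grid$rate <- pmax(rate, 0)
  truth$preferred <- preferred
  list(table = grid[, RECORDING_COLS], truth = truth)
}

#' Classify each neuron's preferred stimulus
#'
#' The preferred stimulus is the argmax of the neuron's stimulus-mean
#' response (averaged over time bins) in the reference task -- the fixation
#' task by default, since it is the task-neutral condition that also
#' anchors the normalisation.  Ties go to the lowest index.
#'
#' @param table a recording table.
#' @param task reference task.
#' @return a `data.frame` with columns `neuron_id`, `preferred`.
#' @export
classify_preferred_stimulus <- function(table, task = "fixation") {
  check_recording_table(table)
  sub <- table[table$task == task, ]
  if (!nrow(sub)) stop("task '", task, "' not present", call. = FALSE)
  all_stim <- sort(unique(table$stimulus))
  by_ns <- stats::aggregate(rate ~ neuron_id + stimulus, data = sub,
                            FUN = mean)
  gaps <- stats::aggregate(stimulus ~ neuron_id, data = by_ns,
                           FUN = length)
  bad <- gaps$neuron_id[gaps$stimulus != length(all_stim)]
  if (length(bad))
    stop("missing stimuli for neuron(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  neurons <- sort(unique(by_ns$neuron_id))
  preferred <- vapply(neurons, function(nid) {
    rows <- by_ns[by_ns$neuron_id == nid, ]
    rows <- rows[order(rows$stimulus), ]
    rows$stimulus[which.max(rows$rate)]
  }, numeric(1))
  data.frame(neuron_id = neurons, preferred = as.integer(preferred))
}

#' Normalise rates by each neuron's maximum fixation response
#'
#' Divides every rate of a neuron (in all tasks) by that neuron's maximum
#' rate in the fixation task, so the post-normalisation fixation maximum is
#' exactly 1 per neuron.  Neurons with a zero fixation maximum are dropped
#' with a warning.
#'
#' @param table a recording table.
#' @return the normalised recording table.
#' @export
normalize_rates <- function(table) {
  check_recording_table(table)
  fix <- table[table$task == "fixation", ]
  if (!nrow(fix)) stop("fixation task required for normalisation",
                       call. = FALSE)
  mx <- tapply(fix$rate, fix$neuron_id, max)
  zero <- names(mx)[mx <= 0]
  if (length(zero)) {
    warning("dropping ", length(zero),
            " neuron(s) with zero fixation maximum")
    table <- table[!(as.character(table$neuron_id) %in% zero), ]
    mx <- mx[!(names(mx) %in% zero)]
  }
  missing <- !(as.character(table$neuron_id) %in% names(mx))
  if (any(missing)) stop("neuron(s) lack fixation rows", call. = FALSE)
  table$rate <- table$rate / as.numeric(mx[as.character(table$neuron_id)])
  table
}

#' Population activity profile for one (task, stimulus, time bin)
#'
#' Element `k` is the mean (normalised) rate over neurons whose preferred
#' stimulus is `k`, i.e. the population response expressed as a vector over
#' preferred-stimulus groups.  Empty groups yield `NA`.
#'
#' @param table a (normalised) recording table.
#' @param task,stimulus_index,time_bin the cell to profile.
#' @param preferences output of [classify_preferred_stimulus()]; computed
#'   from the table when omitted.
#' @param n_groups number of preferred-stimulus groups (11).
#' @return numeric vector of length `n_groups`.
#' @export
population_profile <- function(table, task, stimulus_index, time_bin,
                               preferences = NULL, n_groups = 11L) {
  check_recording_table(table)
  if (is.null(preferences)) preferences <- classify_preferred_stimulus(table)
  sub <- table[table$task == task & table$stimulus == stimulus_index &
                 table$time_bin_ms == time_bin, ]
  pref <- preferences$preferred[match(sub$neuron_id,
                                      preferences$neuron_id)]
  out <- rep(NA_real_, n_groups)
  means <- tapply(sub$rate, factor(pref, levels = seq_len(n_groups)), mean)
  out[as.integer(names(means))] <- as.numeric(means)
  out
}

#' Gaussian fit of an 11-point population profile
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 * sigma^2))` over
#' `x = 1..11` (linear, not circular: the sample stimuli span a red-green
#' line).  Multi-start initialisation (`mu0` at the argmax and at the
#' rate-weighted mean); the best-RSS converged fit is returned.  A fit is
#' flagged unreliable when the peak locus falls outside `[1, 11]` -- the
#' boundary effect that motivates excluding the extreme stimuli downstream.
#'
#' @param profile numeric vector over preferred-stimulus positions
#'   (`NA`s allowed; at least 5 finite values required).
#' @param x positions (default `seq_along(profile)`).
#' @return an object of class `population_profile_fit` with fields
#'   `peak_locus`, `amplitude`, `width`, `rss`, `converged`, `reliable`.
#' @export
fit_gaussian_profile <- function(profile, x = seq_along(profile)) {
  ok <- is.finite(profile)
  if (sum(ok) < 5L)
    stop("need >= 5 finite profile elements", call. = FALSE)
  xs <- x[ok]; ys <- profile[ok]
  fail <- function() structure(list(peak_locus = NA_real_,
                                    amplitude = NA_real_, width = NA_real_,
                                    rss = NA_real_, converged = FALSE,
                                    reliable = FALSE),
                               class = "population_profile_fit")
  if (stats::sd(ys) < 1e-12) return(fail())  # flat profile: no peak
  w <- pmax(ys - min(ys), 0)
  mu_starts <- unique(c(xs[which.max(ys)],
                        if (sum(w) > 0) sum(w * xs) / sum(w)))
  best <- NULL
  for (mu0 in mu_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        ys ~ A * exp(-(xs - mu)^2 / (2 * sigma^2)),
        start = list(A = max(ys), mu = mu0, sigma = 2),
        lower = c(A = 1e-9, mu = min(xs) - 10, sigma = 1e-3),
        upper = c(A = Inf, mu = max(xs) + 10, sigma = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) return(fail())
  cf <- stats::coef(best$fit)
  structure(list(peak_locus = unname(cf["mu"]),
                 amplitude = unname(cf["A"]),
                 width = unname(cf["sigma"]),
                 rss = best$rss, converged = TRUE,
                 reliable = cf["mu"] >= min(xs) && cf["mu"] <= max(xs)),
            class = "population_profile_fit")
}

#' @export
print.population_profile_fit <- function(x, ...) {
  cat(sprintf(paste0("<population_profile_fit> peak %.3f, amplitude %.3f, ",
                     "width %.3f (%s)\n"),
              x$peak_locus, x$amplitude, x$width,
              if (isTRUE(x$reliable)) "reliable" else "unreliable"))
  invisible(x)
}

## Internal: peak loci for one task over (stimulus, bin); returns matrix
## [stimulus, bin] of fitted peak positions (NA where the fit failed).
peak_locus_matrix <- function(table, task, stimuli, bins, preferences) {
  out <- matrix(NA_real_, length(stimuli), length(bins),
                dimnames = list(stimuli, bins))
  for (si in seq_along(stimuli)) for (bi in seq_along(bins)) {
    prof <- population_profile(table, task, stimuli[si], bins[bi],
                               preferences)
    fit <- tryCatch(fit_gaussian_profile(prof), error = function(e) NULL)
    if (!is.null(fit) && fit$converged)
      out[si, bi] <- fit$peak_locus
  }
  out
}

#' Peak-shift dynamics between two tasks
#'
#' For each stimulus 2..10 (the extremes are excluded because their Gaussian
#' peak estimates suffer boundary effects) and each time bin, the difference
#' of fitted population-profile peak loci between `task_a` and `task_b`
#' (`task_a - task_b`; positive = toward green/index 11).  Each stimulus's
#' curve is divided by the absolute difference at the 100 ms bin; when that
#' value is below `norm_floor` the stimulus is reported unnormalised and
#' flagged.
#'
#' @param table a recording table (normalised internally).
#' @param task_a,task_b the two tasks to difference.
#' @param preferences optional precomputed preferences (defaults to
#'   fixation-task classification of `table`).
#' @param stimuli stimulus indices to analyse (2..10 by default).
#' @param norm_bin normalisation bin centre in ms.
#' @param norm_floor minimum |difference| (index units) for normalisation.
#' @return an object of class `peak_shift_curve`: a list with `curve` (a
#'   `data.frame` with columns `stimulus`, `time_bin_ms`, `shift_raw`,
#'   `shift`, `normalized`), `norm_values`, and the two task names.
#' @export
peak_shift_dynamics <- function(table, task_a = "categorization",
                                task_b = "discrimination",
                                preferences = NULL,
                                stimuli = 2:10, norm_bin = 100,
                                norm_floor = 1e-3) {
  check_recording_table(table)
  for (tk in c(task_a, task_b))
    if (!any(table$task == tk)) stop("task '", tk, "' not present",
                                     call. = FALSE)
  bins <- sort(unique(table$time_bin_ms))
  if (!(norm_bin %in% bins))
    stop("normalisation bin ", norm_bin, " ms not present", call. = FALSE)
  if (is.null(preferences)) preferences <- classify_preferred_stimulus(table)
  table <- normalize_rates(table)
  pk_a <- peak_locus_matrix(table, task_a, stimuli, bins, preferences)
  pk_b <- peak_locus_matrix(table, task_b, stimuli, bins, preferences)
  d <- pk_a - pk_b
  norm_vals <- abs(d[, as.character(norm_bin)])
  flagged <- !is.finite(norm_vals) | norm_vals < norm_floor
  shift <- d / ifelse(flagged, 1, norm_vals)
  curve <- data.frame(
    stimulus = rep(stimuli, times = length(bins)),
    time_bin_ms = rep(bins, each = length(stimuli)),
    shift_raw = as.vector(d),
    shift = as.vector(shift),
    normalized = rep(!flagged, times = length(bins)))
  structure(list(curve = curve,
                 norm_values = stats::setNames(norm_vals, stimuli),
                 norm_bin = norm_bin, task_a = task_a, task_b = task_b,
                 stimuli = stimuli, bins = bins),
            class = "peak_shift_curve")
}

#' @export
print.peak_shift_curve <- function(x, ...) {
  cat(sprintf(paste0("<peak_shift_curve> %s - %s: %d stimuli x %d bins, ",
                     "%d unnormalised\n"),
              x$task_a, x$task_b, length(x$stimuli), length(x$bins),
              sum(!x$curve$normalized) / length(x$bins)))
  invisible(x)
}

#' Bootstrap SD of the peak-shift curve
#'
#' Resamples neurons with replacement (keeping the original
#' preferred-stimulus assignment, so the error bars reflect sampling of
#' neurons, not re-classification noise), recomputes the full peak-shift
#' pipeline on each resample, and returns the SD over resamples for every
#' (stimulus, bin) point, both on the normalised-curve scale and on the raw
#' index-unit scale.
#'
#' @param table a recording table.
#' @param task_a,task_b tasks, as in [peak_shift_dynamics()].
#' @param n_resamples number of bootstrap resamples (>= 2; 100 typical).
#' @param preferences optional precomputed preferences.
#' @param ... passed to [peak_shift_dynamics()].
#' @return a `data.frame` with columns `stimulus`, `time_bin_ms`, `sd_shift`,
#'   `sd_raw`.
#' @export
bootstrap_peak_sd <- function(table, task_a = "categorization",
                              task_b = "discrimination",
                              n_resamples = 100L, preferences = NULL, ...) {
  check_scalar(n_resamples, "n_resamples", lower = 2, integer = TRUE)
  check_recording_table(table)
  if (is.null(preferences)) preferences <- classify_preferred_stimulus(table)
  neurons <- preferences$neuron_id
  rows_by_neuron <- split(seq_len(nrow(table)), table$neuron_id)
  draws <- vector("list", n_resamples)
  for (b in seq_len(n_resamples)) {
    pick <- sample(length(neurons), replace = TRUE)
    idx_list <- rows_by_neuron[as.character(neurons[pick])]
    new_tab <- table[unlist(idx_list), ]
    # relabel duplicates so each resampled copy is its own neuron
    new_tab$neuron_id <- rep(seq_along(pick),
                             times = lengths(idx_list))
    new_pref <- data.frame(neuron_id = seq_along(pick),
                           preferred = preferences$preferred[pick])
    res <- peak_shift_dynamics(new_tab, task_a, task_b,
                               preferences = new_pref, ...)
    draws[[b]] <- res$curve[, c("shift", "shift_raw")]
  }
  template <- peak_shift_dynamics(table, task_a, task_b,
                                  preferences = preferences, ...)$curve
  sd_na <- function(v) if (sum(is.finite(v)) >= 2)
    stats::sd(v[is.finite(v)]) else NA_real_
  shift_mat <- sapply(draws, `[[`, "shift")
  raw_mat <- sapply(draws, `[[`, "shift_raw")
  data.frame(stimulus = template$stimulus,
             time_bin_ms = template$time_bin_ms,
             sd_shift = apply(shift_mat, 1L, sd_na),
             sd_raw = apply(raw_mat, 1L, sd_na))
}

#' Late-window boundary consistency of a peak-shift curve
#'
#' Averages the (normalised) shifts over a late time window per stimulus and
#' locates the category boundary as the stimulus position where the mean
#' shift changes sign (linear interpolation between the adjacent
#' opposite-sign stimuli).  Shifts away from the boundary -- negative
#' (toward red) below it, positive (toward green) above -- are the expected
#' signature.
#'
#' @param curve a [peak_shift_dynamics()] result.
#' @param late_window `c(lo, hi)` window in ms (450-550 by default).
#' @return a list with `window_mean` (a `data.frame` of per-stimulus means)
#'   and `crossing` (interpolated boundary position, or `NA` when the curve
#'   does not change sign).
#' @export
boundary_consistency <- function(curve, late_window = c(450, 550)) {
  stopifnot(inherits(curve, "peak_shift_curve"), length(late_window) == 2L)
  cc <- curve$curve
  sel <- cc$time_bin_ms >= late_window[1] & cc$time_bin_ms <= late_window[2]
  if (!any(sel)) stop("late window contains no time bins", call. = FALSE)
  m <- tapply(cc$shift[sel], cc$stimulus[sel],
              function(v) mean(v[is.finite(v)]))
  stim <- as.numeric(names(m))
  vals <- as.numeric(m)
  crossing <- NA_real_
  for (i in seq_len(length(vals) - 1L)) {
    v1 <- vals[i]; v2 <- vals[i + 1L]
    if (is.finite(v1) && is.finite(v2) && v1 < 0 && v2 > 0) {
      crossing <- stim[i] + (0 - v1) / (v2 - v1) * (stim[i + 1L] - stim[i])
      break
    }
  }
  list(window_mean = data.frame(stimulus = stim, mean_shift = vals),
       crossing = crossing)
}
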