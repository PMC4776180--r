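# Experiment drivers replicating four signatures of categorical processing:
# (i) task-dependent gain modulation of single-unit tuning, (ii) clustering
# of population representations toward focal colours, (iii) drift of
# memorised hues toward the nearest category centre, and (iv) a
# category-dependent discrimination-threshold profile.  All four are driven
# by one shared default parameterization (default_model()).

#' Shared default model configuration
#'
#' One parameterization drives all phenomena: 300 hue units with von Mises
#' tuning (`kappa = 2`, `gain = 1`), three equally spaced categories
#' (`kappa_cat = 4`), sensory noise of 10 degrees, lateral weight
#' `lambda_hue = 0.7`, and top-down weight `lambda_cat = 0.3 * gain` during
#' categorization versus `0` during discrimination.  Early/late readout
#' steps are 2 and 20.
#'
#' @param n_units number of hue-selective units.
#' @return a list with components `population`, `categories`, `params_cat`,
#'   `params_disc`, `noise_sd`, `early_step`, `late_step`.
#' @export
default_model <- function(n_units = 300L) {
  pop <- hue_population(n_units, kappa = 2, gain = 1)
  cats <- category_set(3L, kappa_cat = 4)
  list(population = pop,
       categories = cats,
       params_cat = network_params(lambda_hue = 0.7,
                                   lambda_cat = 0.3 * pop$gain,
                                   topdown_kappa = cats$kappa_cat),
       params_disc = network_params(lambda_hue = 0.7, lambda_cat = 0,
                                    topdown_kappa = cats$kappa_cat),
       noise_sd = deg2rad(10),
       early_step = 2L,
       late_step = 20L)
}

#' Task-dependent gain modulation of single-unit tuning
#'
#' Measures every unit's trial-averaged late response to a grid of stimuli
#' under two task conditions that differ only in the top-down weight
#' (categorization: `lambda_cat > 0`; discrimination: `lambda_cat = 0`),
#' then quantifies, per unit, the Pearson correlation between the two
#' tuning curves, the response-amplitude difference (mean over stimuli,
#' categorization minus discrimination), and the shift in preferred
#' stimulus (signed circular difference of the argmax stimuli).
#'
#' @param population,categories model components.
#' @param params_cat,params_disc [network_params()] for the two conditions;
#'   they must differ only in `lambda_cat`.
#' @param n_stimuli number of grid stimuli (>= 3).
#' @param n_trials noise draws per stimulus.
#' @param time_step readout step (late response).
#' @param noise_sd sensory noise SD in radians.
#' @return an object of class `gain_modulation_result` with per-unit vectors
#'   `correlation`, `amplitude_diff`, `preferred_shift_rad`, the two tuning
#'   matrices, and scalar summaries.
#' @export
run_gain_modulation <- function(population, categories, params_cat,
                                params_disc, n_stimuli = 72L,
                                n_trials = 100L, time_step = 20L,
                                noise_sd = deg2rad(10)) {
  if (n_stimuli < 3L) stop("need >= 3 stimuli for tuning correlations",
                           call. = FALSE)
  if (params_cat$lambda_hue != params_disc$lambda_hue ||
      params_cat$topdown_kappa != params_disc$topdown_kappa ||
      params_cat$rectify != params_disc$rectify)
    stop("conditions must differ only in lambda_cat", call. = FALSE)
  tune_cat <- effective_tuning_at_step(population, categories, params_cat,
                                       time_step, n_trials, noise_sd,
                                       n_stimuli)
  tune_disc <- effective_tuning_at_step(population, categories, params_disc,
                                        time_step, n_trials, noise_sd,
                                        n_stimuli)
  grid <- tune_cat$stimulus_grid
  m_cat <- tune_cat$mean_rates
  m_disc <- tune_disc$mean_rates
  correlation <- vapply(seq_len(population$n), function(i)
    stats::cor(m_cat[i, ], m_disc[i, ]), numeric(1))
  amplitude_diff <- rowMeans(m_cat) - rowMeans(m_disc)
  pref_cat <- grid[max.col(m_cat, ties.method = "first")]
  pref_disc <- grid[max.col(m_disc, ties.method = "first")]
  shift <- circ_dist(pref_cat, pref_disc)
  structure(list(stimulus_grid = grid,
                 tuning_categorization = m_cat,
                 tuning_discrimination = m_disc,
                 correlation = correlation,
                 amplitude_diff = amplitude_diff,
                 preferred_shift_rad = shift,
                 mean_amplitude_diff = mean(amplitude_diff),
                 median_correlation = stats::median(correlation),
                 mean_shift_rad = mean(shift)),
            class = "gain_modulation_result")
}

#' @export
print.gain_modulation_result <- function(x, ...) {
  cat(sprintf(paste0("<gain_modulation_result> %d units: mean amplitude ",
                     "diff %.4g, median tuning cor %.4f, mean preferred ",
                     "shift %.3f deg\n"),
              length(x$correlation), x$mean_amplitude_diff,
              x$median_correlation, rad2deg(x$mean_shift_rad)))
  invisible(x)
}

## within/between mean pairwise distance ratio of 2D points
clustering_index <- function(points, membership) {
  stopifnot(nrow(points) == length(membership))
  d <- as.matrix(stats::dist(points))
  same <- outer(membership, membership, "==")
  diag(same) <- NA
  upper <- upper.tri(d)
  within <- d[upper & same & !is.na(same)]
  between <- d[upper & !same & !is.na(same)]
  if (!length(within) || !length(between))
    stop("need both within- and between-category pairs", call. = FALSE)
  if (all(d[upper] < 1e-12)) {
    warning("degenerate clustering: all decoded points coincide")
    return(NA_real_)
  }
  mean(within) / mean(between)
}

#' Clustering of population representations
#'
#' Presents `n_stimuli` evenly spaced hues, decodes each trial-averaged late
#' response to a 2D point (population-vector hue as direction, peak activity
#' as radius), and compares mean pairwise distances within versus between
#' the true categories (nearest centre).  A smaller within/between ratio
#' than for the raw stimuli means the representation is clustered toward
#' the focal colours.
#'
#' @param population,categories,params model components.
#' @param n_stimuli number of evenly spaced stimuli
#'   (>= `2 * categories$n`).
#' @param n_trials noise draws per stimulus.
#' @param time_step readout step.
#' @param noise_sd sensory noise SD in radians.
#' @return an object of class `clustering_result` with the decoded points,
#'   decoded hues, the membership, the within/between `index`, and the
#'   corresponding `stimulus_index` of the raw (unit-radius) stimuli.
#' @export
run_clustering <- function(population, categories, params, n_stimuli = 12L,
                           n_trials = 100L, time_step = 20L,
                           noise_sd = deg2rad(10)) {
  if (n_stimuli < 2L * categories$n)
    stop("need at least 2 stimuli per category", call. = FALSE)
  tuning <- effective_tuning_at_step(population, categories, params,
                                     time_step, n_trials, noise_sd,
                                     n_stimuli)
  stimuli <- tuning$stimulus_grid
  decoded_hue <- vapply(seq_len(n_stimuli), function(k)
    decode_population_vector(tuning$mean_rates[, k], population),
    numeric(1))
  height <- apply(tuning$mean_rates, 2L, max)
  membership <- nearest_category(categories, stimuli)
  points <- cbind(height * cos(decoded_hue), height * sin(decoded_hue))
  stim_points <- cbind(cos(stimuli), sin(stimuli))
  structure(list(stimuli = stimuli,
                 decoded_hue = decoded_hue,
                 peak_height = height,
                 membership = membership,
                 points = points,
                 index = clustering_index(points, membership),
                 stimulus_index = clustering_index(stim_points, membership)),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(paste0("<clustering_result> %d stimuli: within/between = ",
                     "%.4f (raw stimuli %.4f)\n"),
              length(x$stimuli), x$index, x$stimulus_index))
  invisible(x)
}

#' Drift of a memorised hue toward the nearest focal colour
#'
#' One (noiseless by default) encoding step at `initial_hue`, followed by
#' `n_steps` recurrence steps with the bottom-up input set to zero -- the
#' memory period, during which the hue units receive only lateral feedback
#' and the top-down categorical signal.  The decoded peak is recorded at
#' every step.
#'
#' @param population,categories,params model components.
#' @param initial_hue presented hue in radians.
#' @param n_steps memory steps after the encoding step (>= 2).
#' @param noise_sd encoding noise SD (default 0: deterministic trajectory).
#' @return an object of class `memory_trajectory` with the per-step decoded
#'   peaks, per-step circular distance to the category centre nearest the
#'   initial hue, and the final distance to the nearest centre.
#' @export
run_memory <- function(population, categories, params, initial_hue,
                       n_steps = 20L, noise_sd = 0) {
  check_scalar(n_steps, "n_steps", lower = 2, integer = TRUE)
  obs <- c(initial_hue, rep(NA_real_, n_steps))
  traj <- run_trial(obs, population, categories, params, noise_sd)
  peaks <- traj$summary$decoded_peak_rad
  target <- categories$centers[nearest_category(categories, initial_hue)]
  dist_target <- circ_dist_abs(peaks, target)
  final_dist <- min(circ_dist_abs(peaks[length(peaks)],
                                  categories$centers))
  structure(list(initial_hue = wrap_angle(initial_hue),
                 target_center = target,
                 decoded_peak_rad = peaks,
                 dist_to_target = dist_target,
                 final_distance = final_dist,
                 trajectory = traj),
            class = "memory_trajectory")
}

#' @export
print.memory_trajectory <- function(x, ...) {
  cat(sprintf(paste0("<memory_trajectory> start %.1f deg, %d steps, final ",
                     "distance to nearest centre %.2f deg\n"),
              rad2deg(x$initial_hue), length(x$decoded_peak_rad),
              rad2deg(x$final_distance)))
  invisible(x)
}

#' Early versus late discrimination-threshold profiles
#'
#' Builds the effective tuning of the network at an early and a late
#' readout step (one simulation, two snapshots) and returns the early
#' threshold profile together with the late profile normalised by it.
#'
#' @param population,categories,params model components.
#' @param early_step,late_step readout steps (`early_step < late_step`).
#' @param n_trials noise draws per grid stimulus.
#' @param noise_sd sensory noise SD in radians.
#' @param grid_size number of grid stimuli.
#' @return a list with `early` (a [threshold_profile()]) and `late` (a
#'   [threshold_profile()] carrying `normalized` = late/early).
#' @export
run_discrimination <- function(population, categories, params,
                               early_step = 2L, late_step = 20L,
                               n_trials = 200L, noise_sd = deg2rad(10),
                               grid_size = 72L) {
  if (early_step >= late_step)
    stop("`early_step` must be smaller than `late_step`", call. = FALSE)
  tunings <- effective_tuning_at_step(population, categories, params,
                                      c(early_step, late_step), n_trials,
                                      noise_sd, grid_size)
  early <- threshold_profile(tunings[[as.character(early_step)]])
  late <- threshold_profile(tunings[[as.character(late_step)]],
                            normalize_by = early)
  list(early = early, late = late)
}

#' Read a threshold profile at specific hues
#'
#' @param profile a [threshold_profile()].
#' @param hues hues in radians (nearest grid point is used).
#' @param normalized read the normalised values instead of the raw ones?
#' @return threshold values at `hues`.
#' @export
threshold_at <- function(profile, hues, normalized = FALSE) {
  stopifnot(inherits(profile, "threshold_profile"))
  vals <- if (normalized) {
    if (is.null(profile$normalized))
      stop("profile has no normalised values", call. = FALSE)
    profile$normalized
  } else profile$threshold
  vals[vapply(hues, function(x)
    which.min(circ_dist_abs(profile$stimulus_grid, x)), integer(1))]
}

#' Category-boundary hues of a category set
#'
#' Midpoints between circularly adjacent category centres.
#'
#' @param cats a [category_set()].
#' @return boundary hues in radians.
#' @export
category_boundaries <- function(cats) {
  ctr <- sort(cats$centers)
  nxt <- c(ctr[-1L], ctr[1L] + 2 * pi)
  wrap_angle((ctr + nxt) / 2)
}
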