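# Ideal-observer analysis: Fisher information of the (effective) population
# code and the derived hue-discrimination threshold profile.

#' Effective tuning container
#'
#' Trial-averaged activity of every unit as a function of the presented
#' stimulus, measured at a fixed post-onset time step -- the "effective"
#' tuning realised by the recurrent network, as opposed to the feedforward
#' tuning curves.
#'
#' @param stimulus_grid evenly spaced stimulus hues covering `[0, 2*pi)`.
#' @param mean_rates units x grid matrix of nonnegative mean rates.
#' @return an object of class `effective_tuning`.
#' @export
effective_tuning <- function(stimulus_grid, mean_rates) {
  stopifnot(is.matrix(mean_rates),
            ncol(mean_rates) == length(stimulus_grid))
  if (any(!is.finite(mean_rates)) || any(mean_rates < 0))
    stop("mean rates must be finite and nonnegative", call. = FALSE)
  spacing <- diff(stimulus_grid)
  if (length(spacing) && max(abs(spacing - spacing[1])) > 1e-9)
    stop("stimulus grid must be evenly spaced", call. = FALSE)
  structure(list(stimulus_grid = stimulus_grid, mean_rates = mean_rates),
            class = "effective_tuning")
}

#' Measure effective tuning of the network at a given time step
#'
#' For every stimulus on an even hue grid, runs the network with that
#' constant stimulus for `time_step` steps and averages the activity at the
#' final step over `n_trials` independent sensory-noise draws.
#'
#' @param population,categories,params model components.
#' @param time_step step at which activity is read out (>= 1); step 2 probes
#'   the early, step 20 the late (near steady-state) response.
#' @param n_trials noise draws per grid stimulus (>= 1).
#' @param noise_sd sensory noise SD in radians.
#' @param grid_size number of grid stimuli.
#' @details One matrix of per-step, per-trial noise offsets is drawn once
#'   and shared by all grid stimuli (common random numbers).  Derivatives
#'   of the mean rates with respect to the stimulus -- the quantity Fisher
#'   information needs -- are then free of trial-resampling jitter: without
#'   the top-down term the trial-averaged tuning is an exact function of
#'   circular distance, so any stimulus dependence that remains is the
#'   categorical signal, not Monte-Carlo noise.
#' @return an [effective_tuning()] object; when `time_step` is a vector, a
#'   named list of them (one network run, snapshots at each step).
#' @export
effective_tuning_at_step <- function(population, categories, params,
                                     time_step = 20L, n_trials = 200L,
                                     noise_sd = deg2rad(10),
                                     grid_size = 72L) {
  check_scalar(n_trials, "n_trials", lower = 1, integer = TRUE)
  check_scalar(grid_size, "grid_size", lower = 4, integer = TRUE)
  if (any(time_step < 1)) stop("`time_step` must be >= 1", call. = FALSE)
  steps <- sort(unique(as.integer(time_step)))
  grid <- 2 * pi * (seq_len(grid_size) - 1L) / grid_size
  mats <- lapply(steps, function(s)
    matrix(NA_real_, population$n, grid_size))
  names(mats) <- as.character(steps)
  offsets <- matrix(stats::rnorm(max(steps) * n_trials, 0, noise_sd),
                    max(steps), n_trials)
  for (k in seq_along(grid)) {
    snaps <- run_trials_matrix(rep(grid[k], max(steps)), population,
                               categories, params, noise_sd, n_trials,
                               snapshot_steps = steps,
                               noise_offsets = offsets)
    for (s in names(snaps)) mats[[s]][, k] <- snaps[[s]]
  }
  out <- lapply(mats, function(m) effective_tuning(grid, m))
  if (length(out) == 1L) out[[1L]] else out
}

#' Fisher information of a population code
#'
#' For Poisson-like statistics, `J(theta) = sum_i f_i'(theta)^2 / f_i(theta)`
#' in units of inverse squared radians.  Derivatives are taken by 4th-order
#' centred finite differences on the circular stimulus grid.  Terms with
#' `f_i = f_i' = 0` contribute zero; `f_i = 0` with a nonzero derivative is a
#' singularity and raises an error.
#'
#' @param tuning an [effective_tuning()].
#' @param hue optional hue(s) at which to evaluate (nearest grid point);
#'   default `NULL` returns the whole profile.
#' @return Fisher information over the grid (or at `hue`).
#' @export
fisher_information <- function(tuning, hue = NULL) {
  stopifnot(inherits(tuning, "effective_tuning"))
  f <- tuning$mean_rates
  g <- ncol(f)
  if (g < 5L) stop("grid too coarse for finite differences", call. = FALSE)
  h <- 2 * pi / g
  idx <- function(k) ((seq_len(g) - 1L + k) %% g) + 1L
  fp <- (-f[, idx(2L), drop = FALSE] + 8 * f[, idx(1L), drop = FALSE] -
           8 * f[, idx(-1L), drop = FALSE] + f[, idx(-2L), drop = FALSE]) /
    (12 * h)
  bad <- f == 0 & fp != 0
  if (any(bad))
    stop("singular Fisher information: zero rate with nonzero derivative",
         call. = FALSE)
  terms <- fp^2 / f
  terms[f == 0] <- 0
  j <- colSums(terms)
  if (is.null(hue)) return(j)
  j[vapply(hue, function(x)
    which.min(circ_dist_abs(tuning$stimulus_grid, x)), integer(1))]
}

#' Asymptotic discrimination threshold from Fisher information
#'
#' In the large-population limit the ideal observer's discrimination
#' threshold is `k / sqrt(J)`; the constant `k` is arbitrary and absorbed by
#' normalisation, so `k = 1` here.
#'
#' @param j Fisher information values (> 0).
#' @return thresholds in radians.
#' @export
discrimination_threshold <- function(j) {
  if (any(!is.finite(j)) || any(j <= 0))
    stop("undefined threshold: Fisher information must be positive",
         call. = FALSE)
  1 / sqrt(j)
}

#' Discrimination-threshold profile over the hue circle
#'
#' Applies [fisher_information()] then [discrimination_threshold()] across
#' the stimulus grid; optionally divides pointwise by a reference profile
#' (e.g. the early-response profile, as in the normalised late/early
#' comparison).
#'
#' @param tuning an [effective_tuning()].
#' @param normalize_by optional `threshold_profile` on the same grid.
#' @return an object of class `threshold_profile` with fields
#'   `stimulus_grid`, `threshold` and (when normalised) `normalized`.
#' @export
threshold_profile <- function(tuning, normalize_by = NULL) {
  thr <- discrimination_threshold(fisher_information(tuning))
  out <- list(stimulus_grid = tuning$stimulus_grid, threshold = thr,
              normalized = NULL)
  if (!is.null(normalize_by)) {
    stopifnot(inherits(normalize_by, "threshold_profile"))
    if (length(normalize_by$stimulus_grid) != length(out$stimulus_grid) ||
        max(circ_dist_abs(normalize_by$stimulus_grid,
                          out$stimulus_grid)) > 1e-9)
      stop("grid mismatch between profile and its normaliser",
           call. = FALSE)
    out$normalized <- thr / normalize_by$threshold
  }
  structure(out, class = "threshold_profile")
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf("<threshold_profile> %d stimuli, threshold range [%.4g, %.4g]",
              length(x$stimulus_grid), min(x$threshold), max(x$threshold)))
  if (!is.null(x$normalized))
    cat(sprintf(", normalized range [%.4g, %.4g]",
                min(x$normalized), max(x$normalized)))
  cat("\n")
  invisible(x)
}
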