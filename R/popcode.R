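# Core domain objects: the hue-selective population, the category set, the
# hierarchical generative model of stimulus sequences, and stimulus encoding.

#' Bank of hue-selective units with von Mises tuning
#'
#' Constructs a population of `n_units` hue-selective units whose preferred
#' hues are evenly spaced on the hue circle (`2*pi*i/n_units`,
#' `i = 0 .. n_units - 1`).  Each unit's tuning curve is an unnormalised von
#' Mises bump `gain * exp(kappa * (cos(s - theta_i) - 1))`, so `gain` is the
#' peak firing rate and `kappa` controls tuning width (half-width at half
#' maximum about 48 degrees for `kappa = 2`, plausible for IT colour cells).
#'
#' @param n_units number of units (>= 3); 300 by default, matching the
#'   simulated network scale.
#' @param kappa tuning sharpness (> 0).
#' @param gain peak firing rate in arbitrary rate units (> 0).
#' @return an object of class `hue_population` with fields `preferred_hues`,
#'   `kappa`, `gain`, `n`.
#' @examples
#' pop <- hue_population(8)
#' pop$preferred_hues
#' @export
hue_population <- function(n_units = 300L, kappa = 2, gain = 1) {
  check_scalar(n_units, "n_units", lower = 3, integer = TRUE)
  check_scalar(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  n_units <- as.integer(n_units)
  structure(
    list(preferred_hues = 2 * pi * (seq_len(n_units) - 1L) / n_units,
         kappa = kappa, gain = gain, n = n_units),
    class = "hue_population")
}

#' @export
print.hue_population <- function(x, ...) {
  cat(sprintf("<hue_population> %d units, kappa = %g, gain = %g\n",
              x$n, x$kappa, x$gain))
  invisible(x)
}

#' Set of colour categories on the hue circle
#'
#' A category is defined by its focal hue (centre) and the concentration of
#' the category-conditional hue distribution `p(s | c)`, modelled as a von
#' Mises density around the centre.  By default three categories are spaced
#' equally around the circle.
#'
#' @param n number of categories (>= 2).
#' @param centers focal hues in radians; defaults to `2*pi*(0:(n-1))/n`.
#' @param kappa_cat concentration of `p(s | c)` (> 0).  The default 4 gives a
#'   circular SD of about 29 degrees, so adjacent 120-degree categories are
#'   well separated with modest overlap.
#' @return an object of class `category_set`.
#' @export
category_set <- function(n = 3L, centers = NULL, kappa_cat = 4) {
  check_scalar(n, "n", lower = 2, integer = TRUE)
  check_scalar(kappa_cat, "kappa_cat", lower = 0, strict_lower = TRUE)
  n <- as.integer(n)
  if (is.null(centers)) centers <- 2 * pi * (seq_len(n) - 1L) / n
  if (length(centers) != n || any(!is.finite(centers)))
    stop("`centers` must be ", n, " finite angles", call. = FALSE)
  centers <- wrap_angle(centers)
  if (anyDuplicated(round(centers, 12)))
    stop("category centers must be distinct modulo 2*pi", call. = FALSE)
  structure(list(centers = centers, kappa_cat = kappa_cat, n = n),
            class = "category_set")
}

#' @export
print.category_set <- function(x, ...) {
  cat(sprintf("<category_set> %d categories at {%s} deg, kappa_cat = %g\n",
              x$n, paste(round(rad2deg(x$centers), 1), collapse = ", "),
              x$kappa_cat))
  invisible(x)
}

#' Nearest category centre
#'
#' @param cats a [category_set()].
#' @param hue angles in radians (vectorised).
#' @return integer indices of the circularly nearest centre (ties broken by
#'   lowest index).
#' @export
nearest_category <- function(cats, hue) {
  d <- outer(hue, cats$centers, circ_dist_abs)
  apply(d, 1L, which.min)
}

#' Hierarchical generative model configuration
#'
#' The environment model behind the inference problem: a colour category
#' evolves as a slow Markov chain (probability `switch_prob` of jumping,
#' uniformly, to another category at each step), the hue at each step is
#' drawn from the von Mises emission of the active category, and the sensory
#' observation is the hue corrupted by wrapped-Gaussian noise.
#'
#' @param categories a [category_set()].
#' @param switch_prob per-step category switch probability in `[0, 1)`.
#' @param obs_noise_sd SD of the wrapped-Gaussian observation noise in
#'   radians; the default corresponds to 10 azimuth degrees.
#' @param horizon sequence length in steps (>= 1).
#' @return an object of class `generative_config`.
#' @export
generative_config <- function(categories = category_set(),
                              switch_prob = 0.02,
                              obs_noise_sd = deg2rad(10),
                              horizon = 20L) {
  stopifnot(inherits(categories, "category_set"))
  check_scalar(switch_prob, "switch_prob", lower = 0, upper = 1)
  if (switch_prob >= 1) stop("`switch_prob` must be < 1", call. = FALSE)
  check_scalar(obs_noise_sd, "obs_noise_sd", lower = 0)
  check_scalar(horizon, "horizon", lower = 1, integer = TRUE)
  structure(list(categories = categories, switch_prob = switch_prob,
                 obs_noise_sd = obs_noise_sd, horizon = as.integer(horizon)),
            class = "generative_config")
}

#' von Mises tuning curve
#'
#' Peak-normalised von Mises tuning:
#' `gain * exp(kappa * (cos(stimulus_hue - preferred_hue) - 1))`.
#' The maximum value is `gain`, attained iff the stimulus equals the
#' preferred hue modulo `2*pi`; the function is `2*pi`-periodic in both
#' angle arguments.
#'
#' @param stimulus_hue stimulus angle(s) in radians.
#' @param preferred_hue preferred angle(s) in radians.
#' @param kappa tuning sharpness (> 0).
#' @param gain peak rate (> 0).
#' @return firing rates, recycled over the angle arguments.
#' @export
von_mises_tuning <- function(stimulus_hue, preferred_hue, kappa, gain) {
  check_scalar(kappa, "kappa", lower = 0, strict_lower = TRUE)
  check_scalar(gain, "gain", lower = 0, strict_lower = TRUE)
  if (any(!is.finite(stimulus_hue)) || any(!is.finite(preferred_hue)))
    stop("angles must be finite", call. = FALSE)
  gain * exp(kappa * (cos(stimulus_hue - preferred_hue) - 1))
}

#' Noiseless population response to a stimulus
#'
#' @param population a [hue_population()].
#' @param stimulus_hue a single stimulus angle in radians.
#' @return numeric vector of length `population$n`; element `i` is the von
#'   Mises tuning of unit `i` evaluated at the stimulus.
#' @export
population_tuning <- function(population, stimulus_hue) {
  stopifnot(inherits(population, "hue_population"))
  check_scalar(stimulus_hue, "stimulus_hue")
  von_mises_tuning(stimulus_hue, population$preferred_hues,
                   population$kappa, population$gain)
}

#' Encode a stimulus with sensory noise
#'
#' Perturbs the stimulus hue by a wrapped-Gaussian draw of SD `noise_sd`
#' (the front-end noise of the model, 10 degrees by default elsewhere) and
#' returns the noiseless population response at the perturbed hue.
#' Deterministic given the R random seed.
#'
#' @param population a [hue_population()].
#' @param stimulus_hue stimulus angle in radians.
#' @param noise_sd noise SD in radians (>= 0); 0 reduces to
#'   [population_tuning()].
#' @return numeric activity vector of length `population$n`.
#' @export
encode_stimulus <- function(population, stimulus_hue, noise_sd) {
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(stimulus_hue, "stimulus_hue")
  perturbed <- rwrapnorm(1L, stimulus_hue, noise_sd)
  population_tuning(population, perturbed)
}

#' Sample a category/hue/observation sequence from the generative model
#'
#' The category follows the Markov chain of `config` (stay with probability
#' `1 - switch_prob`, otherwise move uniformly to one of the other
#' categories); the hue is drawn fresh each step from the von Mises emission
#' of the active category; the observation adds wrapped-Gaussian noise.
#'
#' @param config a [generative_config()].
#' @return a `data.frame` with columns `step`, `category`, `hue_rad`,
#'   `observation_rad`, one row per step.
#' @examples
#' set.seed(1)
#' seqs <- generate_stimulus_sequence(generative_config(horizon = 5))
#' @export
generate_stimulus_sequence <- function(config) {
  stopifnot(inherits(config, "generative_config"))
  cats <- config$categories
  h <- config$horizon
  category <- integer(h)
  category[1L] <- sample.int(cats$n, 1L)
  if (h > 1L) {
    switches <- stats::runif(h - 1L) < config$switch_prob
    for (t in 2L:h) {
      if (switches[t - 1L]) {
        others <- setdiff(seq_len(cats$n), category[t - 1L])
        category[t] <- others[sample.int(length(others), 1L)]
      } else category[t] <- category[t - 1L]
    }
  }
  hue <- numeric(h)
  for (c_idx in unique(category)) {
    sel <- category == c_idx
    hue[sel] <- rvonmises(sum(sel), cats$centers[c_idx], cats$kappa_cat)
  }
  observation <- rwrapnorm(h, hue, config$obs_noise_sd)
  data.frame(step = seq_len(h), category = category,
             hue_rad = hue, observation_rad = observation)
}
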