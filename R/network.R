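# The recurrent inference network: bottom-up category readout with
# winner-take-all competition, top-down categorical signal, the three-term
# activity update, trial runner, decoders, and the exact grid-filtering
# oracle for the hierarchical hidden Markov model.

#' Recurrent network parameters
#'
#' The two modulation weights are effectively the only tunable parameters of
#' the model: `lambda_hue` scales the lateral self-feedback implementing the
#' continuity prior, `lambda_cat` scales the top-down signal implementing the
#' categorical prior.  Task context is modelled by `lambda_cat`: positive
#' during categorization, zero during fine discrimination.
#'
#' @param lambda_hue lateral self-feedback weight in `[0, 1)` (required for
#'   bounded activity under constant input).
#' @param lambda_cat top-down categorical weight (>= 0), in units of the
#'   population gain.
#' @param topdown_kappa sharpness of the bell-shaped top-down profile
#'   (> 0); defaults to the categorical-prior concentration it encodes.
#' @param rectify clip activities at zero (firing rates are nonnegative)?
#'   Rectification never binds in the default regime.
#' @return an object of class `network_params`.
#' @export
network_params <- function(lambda_hue = 0.7, lambda_cat = 0.3,
                           topdown_kappa = 4, rectify = TRUE) {
  check_scalar(lambda_hue, "lambda_hue", lower = 0, upper = 1)
  if (lambda_hue >= 1) stop("`lambda_hue` must be < 1", call. = FALSE)
  check_scalar(lambda_cat, "lambda_cat", lower = 0)
  check_scalar(topdown_kappa, "topdown_kappa", lower = 0, strict_lower = TRUE)
  stopifnot(is.logical(rectify), length(rectify) == 1L)
  structure(list(lambda_hue = lambda_hue, lambda_cat = lambda_cat,
                 topdown_kappa = topdown_kappa, rectify = rectify),
            class = "network_params")
}

#' Fresh network state
#'
#' @param population a [hue_population()].
#' @return a `network_state` with zero activity, no category estimate, step 0.
#' @export
network_state <- function(population) {
  stopifnot(inherits(population, "hue_population"))
  structure(list(activity = numeric(population$n),
                 category_estimate = NA_integer_, step = 0L),
            class = "network_state")
}

#' Bottom-up drive to the category-selective units
#'
#' Linear readout `u_c = sum_i w_ci r_i` with weights
#' `w_ci = kappa_cat * cos(theta_i - mu_c)` -- the log of the
#' category-conditional von Mises up to an additive constant, which cancels
#' in the winner-take-all argmax.
#'
#' @param activity hue-population activity vector.
#' @param population a [hue_population()] aligned with `activity`.
#' @param categories a [category_set()].
#' @return numeric vector of `categories$n` category drives.
#' @export
category_input <- function(activity, population, categories) {
  stopifnot(inherits(population, "hue_population"),
            inherits(categories, "category_set"))
  if (length(activity) != population$n)
    stop("activity length does not match population size", call. = FALSE)
  w <- categories$kappa_cat *
    cos(outer(categories$centers, population$preferred_hues, "-"))
  as.vector(w %*% activity)
}

#' Winner-take-all category estimate
#'
#' @param drives vector of category drives (length >= 2, finite).
#' @return index of the maximal drive; ties broken by lowest index.
#' @export
estimate_category <- function(drives) {
  if (length(drives) < 2L || any(!is.finite(drives)))
    stop("`drives` must be >= 2 finite values", call. = FALSE)
  which.max(drives)
}

#' Top-down categorical signal
#'
#' Bell-shaped feedback from the winning category-selective unit to the hue
#' population: element `i` is
#' `lambda_cat * exp(topdown_kappa * (cos(theta_i - mu_c) - 1))`,
#' peaked at the focal hue of the estimated category.
#'
#' @param category_estimate index into `categories$centers`.
#' @param population a [hue_population()].
#' @param categories a [category_set()].
#' @param params a [network_params()].
#' @return numeric vector of length `population$n` (all zero when
#'   `lambda_cat = 0`).
#' @export
top_down_signal <- function(category_estimate, population, categories,
                            params) {
  stopifnot(inherits(params, "network_params"))
  if (!is.numeric(category_estimate) || length(category_estimate) != 1L ||
      is.na(category_estimate) || category_estimate < 1 ||
      category_estimate > categories$n)
    stop("invalid category index", call. = FALSE)
  mu <- categories$centers[category_estimate]
  params$lambda_cat *
    exp(params$topdown_kappa * (cos(population$preferred_hues - mu) - 1))
}

#' One recurrence step of the network
#'
#' Implements the three-term update: (1) the category is estimated by
#' winner-take-all on the drives computed from the *current* activity (the
#' previous step's posterior); (2) the new activity is
#' `bottom_up + lambda_hue * activity + top_down_signal(c_hat)`;
#' (3) negative values are clipped at zero when `params$rectify`.
#' While the current activity is identically zero there is no evidence, so
#' no category is estimated and the top-down term is omitted.
#'
#' @param state a [network_state()].
#' @param bottom_up sensory input vector (e.g. from [encode_stimulus()]), or
#'   a zero vector for memory-period steps.
#' @param population,categories,params model components.
#' @return the updated `network_state` (step incremented, `category_estimate`
#'   set to the estimate used in this update, `NA` if none).
#' @export
update_step <- function(state, bottom_up, population, categories, params) {
  stopifnot(inherits(state, "network_state"),
            inherits(params, "network_params"))
  if (length(bottom_up) != population$n ||
      length(state$activity) != population$n)
    stop("activity/input length does not match population size",
         call. = FALSE)
  if (any(!is.finite(bottom_up))) stop("non-finite bottom-up input",
                                       call. = FALSE)
  if (any(state$activity != 0)) {
    drives <- category_input(state$activity, population, categories)
    c_hat <- estimate_category(drives)
    td <- top_down_signal(c_hat, population, categories, params)
  } else {
    c_hat <- NA_integer_
    td <- 0
  }
  act <- bottom_up + params$lambda_hue * state$activity + td
  if (params$rectify) act <- pmax(act, 0)
  structure(list(activity = act, category_estimate = c_hat,
                 step = state$step + 1L),
            class = "network_state")
}

#' Run the network over a stimulus-observation sequence
#'
#' Iterates [encode_stimulus()] (zero bottom-up input where the observation
#' is `NA`, as in the memory task) followed by [update_step()], recording the
#' decoded activity peak at every step.
#'
#' @param stimulus_observations vector of hue observations in radians; `NA`
#'   entries mean "no input this step".
#' @param population,categories,params model components.
#' @param noise_sd sensory noise SD in radians (default 0: deterministic).
#' @param init_state optional starting [network_state()].
#' @return an object of class `trajectory`: a list with `summary` (a
#'   `data.frame` with columns `step`, `category_estimate`,
#'   `decoded_peak_rad`) and `activity` (step x unit matrix).
#' @export
run_trial <- function(stimulus_observations, population, categories, params,
                      noise_sd = 0, init_state = NULL) {
  n_steps <- length(stimulus_observations)
  if (n_steps < 1L) stop("empty observation sequence", call. = FALSE)
  state <- if (is.null(init_state)) network_state(population) else init_state
  act <- matrix(NA_real_, n_steps, population$n)
  cat_est <- integer(n_steps)
  peaks <- rep(NA_real_, n_steps)
  zero_in <- numeric(population$n)
  for (t in seq_len(n_steps)) {
    obs <- stimulus_observations[t]
    bu <- if (is.na(obs)) zero_in else
      encode_stimulus(population, obs, noise_sd)
    state <- update_step(state, bu, population, categories, params)
    act[t, ] <- state$activity
    cat_est[t] <- state$category_estimate
    if (any(state$activity != 0))
      peaks[t] <- decode_peak(state$activity, population)
  }
  structure(list(summary = data.frame(step = seq_len(n_steps),
                                      category_estimate = cat_est,
                                      decoded_peak_rad = peaks),
                 activity = act,
                 final_state = state),
            class = "trajectory")
}

#' Peak decoder
#'
#' Preferred hue of the unit with maximal activity (ties broken by lowest
#' index).
#'
#' @param activity activity vector.
#' @param population a [hue_population()].
#' @return decoded hue in radians.
#' @export
decode_peak <- function(activity, population) {
  if (length(activity) != population$n)
    stop("activity length does not match population size", call. = FALSE)
  if (all(activity == 0)) stop("undefined peak: all-zero activity",
                               call. = FALSE)
  population$preferred_hues[which.max(activity)]
}

#' Population-vector decoder
#'
#' Circular mean of preferred hues weighted by activity; gives sub-grid
#' resolution and agrees with [decode_peak()] within one grid spacing on
#' unimodal profiles.
#'
#' @param activity activity vector.
#' @param population a [hue_population()].
#' @return decoded hue in radians, `[0, 2*pi)`.
#' @export
decode_population_vector <- function(activity, population) {
  if (length(activity) != population$n)
    stop("activity length does not match population size", call. = FALSE)
  s <- sum(activity * sin(population$preferred_hues))
  c <- sum(activity * cos(population$preferred_hues))
  if (s == 0 && c == 0) stop("undefined peak: zero resultant", call. = FALSE)
  wrap_angle(atan2(s, c))
}

#' Exact online posterior for the hierarchical generative model
#'
#' Forward filtering on the joint (category, hue-grid-cell) chain: the
#' category prior is propagated through the switch transition matrix, hue is
#' re-emitted each step from the category-conditional von Mises (the hue has
#' no dynamics of its own given the category), and the wrapped-Gaussian
#' observation likelihood updates the joint, which is then normalised.  All
#' arithmetic is in the log domain with per-step max subtraction.  This is
#' the exact Bayes filter the recurrent network approximates.
#'
#' @param observations vector of hue observations in radians (no `NA`s).
#' @param config a [generative_config()] (its `horizon` is ignored; the
#'   length of `observations` is used).
#' @param grid_size number of hue grid cells (>= 36 recommended; a warning
#'   is issued below that).
#' @return a list with `grid` (cell centres), `log_hue_posterior`
#'   (steps x grid matrix of log probabilities over cells, each row
#'   normalised), and `category_posterior` (steps x n matrix).
#' @export
exact_online_posterior <- function(observations, config, grid_size = 60L) {
  stopifnot(inherits(config, "generative_config"))
  check_scalar(grid_size, "grid_size", lower = 4, integer = TRUE)
  if (grid_size < 36) warning("hue grid coarser than 36 cells; ",
                              "posterior may be inaccurate")
  if (any(!is.finite(observations)))
    stop("observations must be finite", call. = FALSE)
  cats <- config$categories
  n <- cats$n
  g <- as.integer(grid_size)
  grid <- 2 * pi * (seq_len(g) - 1L) / g
  # log emission p(s | c), normalised over grid cells
  log_emit <- cats$kappa_cat * cos(outer(cats$centers, grid, "-"))
  log_emit <- log_emit - apply(log_emit, 1L, logsumexp)
  # log transition
  p <- config$switch_prob
  trans <- matrix(if (n > 1) p / (n - 1) else 0, n, n)
  diag(trans) <- 1 - p
  log_trans <- log(trans)
  sd <- config$obs_noise_sd
  if (sd <= 0) stop("exact filtering requires obs_noise_sd > 0",
                    call. = FALSE)
  t_max <- length(observations)
  log_post <- matrix(NA_real_, t_max, g)
  cat_post <- matrix(NA_real_, t_max, n)
  log_alpha_cat <- rep(-log(n), n)  # filtered category marginal
  for (t in seq_len(t_max)) {
    log_lik <- log(dwrapnorm(observations[t], grid, sd))
    if (all(!is.finite(log_lik)))
      stop("numerical underflow: zero observation likelihood everywhere",
           call. = FALSE)
    # predict category, then joint over (c, s)
    log_pred <- vapply(seq_len(n), function(cc)
      logsumexp(log_alpha_cat + log_trans[, cc]), numeric(1))
    log_joint <- log_pred + log_emit +
      matrix(log_lik, n, g, byrow = TRUE)
    norm <- logsumexp(log_joint)
    log_joint <- log_joint - norm
    log_post[t, ] <- apply(log_joint, 2L, logsumexp)
    log_alpha_cat <- apply(log_joint, 1L, logsumexp)
    cat_post[t, ] <- exp(log_alpha_cat)
  }
  list(grid = grid, log_hue_posterior = log_post,
       category_posterior = cat_post)
}

## Vectorised multi-trial runner used by the observer and phenomena modules.
## Runs `n_trials` independent trials of the same stimulus sequence as one
## (units x trials) matrix recursion; columns are trials.  `snapshot_steps`
## selects the steps at which the mean activity across trials is recorded.
## `noise_offsets` (n_steps x n_trials), when given, replaces fresh noise
## draws; sharing one offset matrix across grid stimuli implements common
## random numbers, which removes Monte-Carlo jitter from stimulus-derivative
## estimates (the trial-averaged tuning becomes an exact function of
## circular distance when the top-down term is off).
run_trials_matrix <- function(stimulus_observations, population, categories,
                              params, noise_sd, n_trials,
                              snapshot_steps, noise_offsets = NULL) {
  n_steps <- length(stimulus_observations)
  stopifnot(n_steps >= 1L, n_trials >= 1L,
            all(snapshot_steps >= 1L), all(snapshot_steps <= n_steps))
  if (!is.null(noise_offsets))
    stopifnot(nrow(noise_offsets) == n_steps,
              ncol(noise_offsets) == n_trials)
  n_units <- population$n
  pref <- population$preferred_hues
  # precomputed top-down profile per category (units x n)
  td_base <- params$lambda_cat *
    exp(params$topdown_kappa *
          (cos(outer(pref, categories$centers, "-")) - 1))
  w <- categories$kappa_cat * cos(outer(categories$centers, pref, "-"))
  r <- matrix(0, n_units, n_trials)
  out <- vector("list", length(snapshot_steps))
  names(out) <- as.character(snapshot_steps)
  for (t in seq_len(n_steps)) {
    obs <- stimulus_observations[t]
    if (is.na(obs)) {
      bu <- matrix(0, n_units, n_trials)
    } else {
      perturbed <- if (is.null(noise_offsets))
        rwrapnorm(n_trials, obs, noise_sd)
      else wrap_angle(obs + noise_offsets[t, ])
      bu <- population$gain *
        exp(population$kappa * (cos(outer(pref, perturbed, "-")) - 1))
    }
    live <- colSums(r) > 0
    td <- matrix(0, n_units, n_trials)
    if (any(live) && params$lambda_cat > 0) {
      drives <- w %*% r[, live, drop = FALSE]
      c_hat <- max.col(t(drives), ties.method = "first")
      td[, live] <- td_base[, c_hat, drop = FALSE]
    }
    r <- bu + params$lambda_hue * r + td
    if (params$rectify) r[r < 0] <- 0
    hit <- match(t, snapshot_steps)
    if (!is.na(hit)) out[[hit]] <- rowMeans(r)
  }
  out
}
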