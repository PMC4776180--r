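# Recurrent update, winner-take-all readout, decoders, and the exact
# grid-filtering oracle.

test_that("category drives are symmetric for uniform activity", {
  pop <- hue_population(30)
  cats <- category_set()
  u <- category_input(rep(1, 30), pop, cats)
  expect_equal(u, rep(u[1], 3), tolerance = 1e-10)
  expect_error(category_input(rep(1, 29), pop, cats), "length")
})

test_that("category drives pick the right category for tuned activity", {
  pop <- hue_population(30)
  cats <- category_set()
  # activity tuned to each category centre selects that category
  for (c_idx in 1:3) {
    act <- population_tuning(pop, cats$centers[c_idx])
    expect_equal(which.max(category_input(act, pop, cats)), c_idx)
  }
  # a single active unit selects the circularly nearest centre
  for (i in seq_len(pop$n)) {
    act <- numeric(pop$n); act[i] <- 1
    u <- category_input(act, pop, cats)
    expected <- which.min(circ_dist_abs(cats$centers,
                                        pop$preferred_hues[i]))
    # skip exact boundary units, where both drives tie
    if (min(circ_dist_abs(cats$centers, pop$preferred_hues[i])) <
        pi / 3 - 1e-9)
      expect_equal(which.max(u), expected)
  }
})

test_that("winner-take-all is a deterministic argmax with low-index ties", {
  expect_equal(estimate_category(c(1, 3, 2)), 2L)
  expect_equal(estimate_category(c(2, 2, 1)), 1L)
  d <- c(0.3, 2.2, 1.1, 0.9)
  perm <- c(3, 1, 4, 2)
  expect_equal(perm[estimate_category(d[perm])],
               estimate_category(d))
  expect_error(estimate_category(numeric(0)))
  expect_error(estimate_category(c(1, NA, 2)))
})

test_that("top-down signal is a bell at the focal hue, zero when off", {
  pop <- hue_population(30)
  cats <- category_set()
  p_off <- network_params(lambda_cat = 0)
  expect_equal(top_down_signal(2, pop, cats, p_off), rep(0, 30))
  p_on <- network_params(lambda_cat = 0.4, topdown_kappa = 4)
  td <- top_down_signal(1, pop, cats, p_on)
  expect_equal(max(td), 0.4)          # peak value = lambda_cat at centre
  expect_equal(which.max(td), 1L)     # centre 0 is unit 1's preferred hue
  # reflection symmetry about the centre
  expect_equal(td[2], td[30])
  expect_equal(td[8], td[24])
  expect_error(top_down_signal(4, pop, cats, p_on), "invalid")
})

test_that("update_step implements the three-term recurrence", {
  pop <- hue_population(30)
  cats <- category_set()
  bu <- population_tuning(pop, 1.0)
  # pure feedforward
  st <- update_step(network_state(pop), bu, pop, cats,
                    network_params(lambda_hue = 0, lambda_cat = 0))
  expect_equal(st$activity, bu)
  # geometric decay under zero input
  p <- network_params(lambda_hue = 0.6, lambda_cat = 0)
  st <- network_state(pop); st$activity <- bu
  for (k in 1:5) {
    st <- update_step(st, numeric(30), pop, cats, p)
    expect_equal(st$activity, bu * 0.6^k, tolerance = 1e-12)
  }
})

test_that("constant drive converges to the geometric-series fixed point", {
  pop <- hue_population(30)
  cats <- category_set()
  params <- network_params(lambda_hue = 0.7, lambda_cat = 0.3,
                           topdown_kappa = 4)
  bu <- population_tuning(pop, cats$centers[2])
  st <- network_state(pop)
  for (k in 1:200) st <- update_step(st, bu, pop, cats, params)
  expect_equal(st$category_estimate, 2L)
  td <- top_down_signal(2, pop, cats, params)
  fixed_point <- (bu + td) / (1 - params$lambda_hue)
  expect_equal(st$activity, fixed_point, tolerance = 1e-6)
})

test_that("run_trial handles feedforward, empty, and fixed-point cases", {
  pop <- hue_population(30)
  cats <- category_set()
  # single step, no noise, both lambdas zero: peak at nearest grid hue
  tr <- run_trial(2.33, pop, cats,
                  network_params(lambda_hue = 0, lambda_cat = 0))
  expect_equal(tr$summary$decoded_peak_rad,
               pop$preferred_hues[which.min(
                 circ_dist_abs(pop$preferred_hues, 2.33))])
  # all-none observations from a zero state: all-zero trajectory
  tr0 <- run_trial(rep(NA_real_, 5), pop, cats, network_params())
  expect_true(all(tr0$activity == 0))
  expect_true(all(is.na(tr0$summary$decoded_peak_rad)))
  # constant stimulus at a centre: decoded peak pinned there
  trc <- run_trial(rep(cats$centers[3], 10), pop, cats, network_params())
  expect_equal(trc$summary$decoded_peak_rad,
               rep(cats$centers[3], 10), tolerance = 1e-12)
  expect_error(run_trial(numeric(0), pop, cats, network_params()))
})

test_that("decoders agree and are equivariant under rotation", {
  pop <- hue_population(40)
  act <- population_tuning(pop, pop$preferred_hues[9])
  expect_equal(decode_peak(act, pop), pop$preferred_hues[9])
  # rotating the activity vector rotates the decoded hue
  k <- 7
  rot <- act[((seq_len(40) - 1 - k) %% 40) + 1]
  expect_equal(decode_peak(rot, pop),
               wrap_angle(pop$preferred_hues[9] + k * 2 * pi / 40))
  # population vector is exact on symmetric profiles
  for (s in c(0.13, 2.9, 5.11)) {
    a <- population_tuning(pop, s)
    expect_equal(decode_population_vector(a, pop), s, tolerance = 1e-10)
    expect_lt(circ_dist_abs(decode_peak(a, pop),
                            decode_population_vector(a, pop)),
              2 * pi / 40 + 1e-12)
  }
  expect_error(decode_peak(numeric(40), pop), "all-zero")
})

test_that("one-step exact posterior is the plain Bayes product", {
  cats <- category_set(3, kappa_cat = 3)
  cfg <- generative_config(cats, switch_prob = 0.1, obs_noise_sd = 0.3,
                           horizon = 1)
  obs <- 1.7
  post <- exact_online_posterior(obs, cfg, 48)
  g <- post$grid
  emit <- exp(3 * cos(outer(cats$centers, g, "-")))
  emit <- emit / rowSums(emit)
  prior <- colMeans(emit)          # uniform category prior
  lik <- dwrapnorm(obs, g, 0.3)
  direct <- prior * lik / sum(prior * lik)
  expect_equal(exp(post$log_hue_posterior[1, ]), direct,
               tolerance = 1e-12)
})

test_that("filtered posteriors are normalised and match brute-force path sums", {
  cats <- category_set(2, kappa_cat = 2)
  cfg <- generative_config(cats, switch_prob = 0.3, obs_noise_sd = 0.4,
                           horizon = 3)
  obs <- c(0.5, 2.8, 3.1)
  post <- suppressWarnings(exact_online_posterior(obs, cfg, 12))
  for (t in 1:3) {
    expect_equal(sum(exp(post$log_hue_posterior[t, ])), 1,
                 tolerance = 1e-12)
    expect_equal(sum(post$category_posterior[t, ]), 1, tolerance = 1e-12)
  }
  # independent oracle: exhaustive marginalisation over all 2^3 paths
  g <- 12; grid <- 2 * pi * (0:(g - 1)) / g
  emit <- exp(2 * cos(outer(cats$centers, grid, "-")))
  emit <- emit / rowSums(emit)
  lik <- t(sapply(obs, function(o) dwrapnorm(o, grid, 0.4)))
  tm <- matrix(0.3, 2, 2); diag(tm) <- 0.7
  paths <- as.matrix(expand.grid(1:2, 1:2, 1:2))
  p_hue <- numeric(g); total <- 0
  for (r in seq_len(nrow(paths))) {
    cs <- paths[r, ]
    w <- 0.5 * tm[cs[1], cs[2]] * tm[cs[2], cs[3]] *
      sum(emit[cs[1], ] * lik[1, ]) * sum(emit[cs[2], ] * lik[2, ])
    p_hue <- p_hue + w * emit[cs[3], ] * lik[3, ]
    total <- total + w * sum(emit[cs[3], ] * lik[3, ])
  }
  expect_equal(exp(post$log_hue_posterior[3, ]), p_hue / total,
               tolerance = 1e-12)
  expect_warning(exact_online_posterior(obs, cfg, 12), "coarser")
})

test_that("activity stays within the geometric bound", {
  m <- small_model(40)
  bound <- (m$population$gain + m$params_cat$lambda_cat) /
    (1 - m$params_cat$lambda_hue)
  set.seed(31)
  for (rep in 1:5) {
    obs <- runif(30, 0, 2 * pi)
    tr <- run_trial(obs, m$population, m$categories, m$params_cat,
                    noise_sd = m$noise_sd)
    expect_lt(max(tr$activity), bound + 1e-9)
  }
})

test_that("the whole network is rotation-equivariant", {
  n <- 60
  pop <- hue_population(n)
  delta <- 2 * pi * 11 / n   # grid-aligned rotation keeps decoding exact
  cats1 <- category_set()
  cats2 <- category_set(3, centers = category_set()$centers + delta)
  params <- network_params()
  obs <- c(0.4, 0.9, 0.7, 1.2, 1.0)
  tr1 <- run_trial(obs, pop, cats1, params)
  tr2 <- run_trial(obs + delta, pop, cats2, params)
  expect_equal(wrap_angle(tr1$summary$decoded_peak_rad + delta),
               tr2$summary$decoded_peak_rad, tolerance = 1e-9)
})

test_that("the winner-take-all estimate tracks a fixed category", {
  m <- small_model(60)
  gen <- generative_config(m$categories, switch_prob = 0, horizon = 10)
  set.seed(99)
  acc <- replicate(200, {
    seqs <- generate_stimulus_sequence(gen)
    tr <- run_trial(seqs$observation_rad, m$population, m$categories,
                    m$params_cat, noise_sd = 0)
    mean(tr$summary$category_estimate[4:10] == seqs$category[4:10])
  })
  expect_gte(mean(acc), 0.95)
})
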