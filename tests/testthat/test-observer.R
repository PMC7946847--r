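# Observer model: logistic identification, condition modifiers, pair rule,
# response simulation.

test_that("identification probability hits the logistic landmarks", {
  obs <- observer_params(extent_h = 40, slope = 3, guess_rate = 0.2)
  # midpoint: s = E* gives Lambda 0.5, q = 0.2 + 0.8 * 0.5
  expect_equal(identification_probability(mock_trials(40), obs), 0.6)
  # frozen value from direct evaluation of q = 0.2 + 0.8/(1 + exp(-5/3))
  expect_equal(identification_probability(mock_trials(35), obs),
               0.2 + 0.8 / (1 + exp(-5 / 3)), tolerance = 1e-12)
  expect_equal(identification_probability(mock_trials(35), obs), 0.8729047,
               tolerance = 1e-7)
  # step-function limit
  steep <- observer_params(extent_h = 40, slope = 1e-9)
  expect_equal(identification_probability(mock_trials(35), steep), 1)
  expect_equal(identification_probability(mock_trials(45), steep), 0.2)
})

test_that("q is monotone in separation and effective extent", {
  set.seed(21)
  for (i in 1:20) {
    obs <- observer_params(extent_h = runif(1, 10, 45),
                           slope = runif(1, 0.5, 6))
    s <- seq(5, 50, by = 2.5)
    q <- identification_probability(mock_trials(s), obs)
    expect_true(all(diff(q) <= 0))
    bigger <- obs
    bigger$extent_h <- obs$extent_h + runif(1, 1, 10)
    expect_true(all(identification_probability(mock_trials(s), bigger) >= q))
  }
})

test_that("condition modifiers shrink the effective extent multiplicatively", {
  obs <- observer_params()
  base <- effective_extent(mock_trials(20), obs)
  expect_equal(base, obs$extent_h)
  expect_equal(effective_extent(mock_trials(20, cue_validity = "invalid"), obs),
               obs$extent_h * obs$validity_factor)
  expect_equal(effective_extent(mock_trials(20, complexity = "high6"), obs),
               obs$extent_h * obs$complexity_factor)
  # SOA ramp: floor fraction near 0 ms, saturating at soa_t_full_ms
  expect_equal(effective_extent(mock_trials(20, soa_ms = 0), obs),
               obs$extent_h * obs$soa_floor)
  g <- sapply(c(0, 50, 100, 200, 350), function(t) soa_gain(obs, t))
  expect_true(all(diff(g) >= 0))
  expect_equal(g[4], 1)
  expect_equal(g[5], 1)
})

test_that("anisotropy propagates: wider horizontal extent, higher accuracy", {
  obs <- observer_params()  # extent_h > extent_v
  s <- seq(10, 45, 5)
  ph <- pair_correct_probability(mock_trials(s, "horizontal"), obs)
  pv <- pair_correct_probability(mock_trials(s, "vertical"), obs)
  expect_true(all(ph > pv))
})

test_that("pair-correct probability follows the model rules", {
  obs <- observer_params(extent_h = 40, slope = 1e-9)
  expect_equal(pair_correct_probability(mock_trials(10), obs), 1)   # ceiling
  floor_obs <- observer_params(extent_h = 0, extent_v = 0, extent_d = 0,
                               slope = 1e-9)
  expect_equal(pair_correct_probability(mock_trials(20), floor_obs), 0.04)
  # spotlight: shift budget 50 + 10 * 30 = 350 ms exceeds the 300-ms target
  spot <- observer_params(model = "spotlight_shift", shift_base_ms = 50,
                          shift_cost_ms_per_deg = 10)
  q30 <- identification_probability(mock_trials(30), spot)
  expect_equal(pair_correct_probability(mock_trials(30), spot),
               q30 * spot$guess_rate)
  # within budget (50 + 10*20 = 250 < 300) both stimuli get q
  q20 <- identification_probability(mock_trials(20), spot)
  expect_equal(pair_correct_probability(mock_trials(20), spot), q20^2)
})

test_that("the analytic 75 % point solves the pair-correct equation", {
  obs <- observer_params()
  for (m in c("horizontal", "vertical", "diagonal1")) {
    s_star <- analytic_threshold(obs, m)
    expect_equal(pair_correct_probability(mock_trials(s_star, m), obs), 0.75,
                 tolerance = 1e-10)
  }
  # spotlight model has no closed form
  expect_error(analytic_threshold(observer_params(model = "spotlight_shift")),
               "attention_field")
})

test_that("response simulation matches its generative probabilities", {
  cfg <- awt_config()
  trials <- generate_session(cfg, seed = 3)
  # perfect identification: reports equal the true counts
  perfect <- observer_params(extent_h = 500, extent_v = 500, extent_d = 500,
                             slope = 1e-9)
  rec <- simulate_responses(trials, perfect, seed = 1)
  expect_equal(rec$reported_count_a, rec$target_count_a)
  expect_true(all(rec$correct))
  # pure guessing: pair-correct rate at the (1/5)^2 floor
  blind <- observer_params(extent_h = 0, extent_v = 0, extent_d = 0,
                           slope = 1e-9)
  big <- generate_session(awt_config(reps_per_cell = 100), seed = 5)
  guesses <- dplyr::bind_rows(lapply(1:4, function(i) {
    simulate_responses(big, blind, seed = i)
  }))
  expect_lt(abs(mean(guesses$correct) - 0.04), 0.005)
  # determinism
  expect_identical(simulate_responses(trials, perfect, seed = 7),
                   simulate_responses(trials, perfect, seed = 7))
})

test_that("cohort simulation is reproducible with the right dimensions", {
  cohort <- observer_cohort(3, seed = 2)
  expect_named(cohort, c("s01", "s02", "s03"))
  rec <- simulate_cohort(cohort, awt_config(), seed = 9)
  expect_equal(nrow(rec), 3 * 288)
  expect_equal(unname(table(rec$subject)), rep(288L, 3), ignore_attr = TRUE)
  expect_identical(simulate_cohort(cohort, awt_config(), seed = 9), rec)
  # one observer, one-trial design
  one <- simulate_cohort(cohort[1],
                         awt_config(separations_deg = 20,
                                    meridians = "horizontal",
                                    reps_per_cell = 1),
                         seed = 1)
  expect_equal(nrow(one), 1)
  names(cohort) <- c("a", "a", "b")
  expect_error(simulate_cohort(cohort, awt_config(), seed = 1), "unique")
})

test_that("observer parameters are validated", {
  expect_error(observer_params(slope = 0), "positive")
  expect_error(observer_params(validity_factor = 0), "0, 1")
  expect_error(observer_params(validity_factor = 1.1), "0, 1")
  expect_error(observer_params(guess_rate = 1.5), "probability")
})
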