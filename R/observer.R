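# Synthetic observers for the Attention-Window Task.
#
# The default "attention_field" observer identifies each peripheral stimulus
# with a probability that falls off logistically with stimulus separation,
# around a meridian-specific extent that shrinks multiplicatively under
# invalid cueing, short cue-target intervals and higher stimulus complexity.
# The alternative "spotlight_shift" observer processes the two stimuli
# serially and fails on the second when the shift time exceeds the target
# duration.

#' Synthetic observer parameters
#'
#' Generative parameters of one simulated participant. The identification
#' probability of a single stimulus at separation `s` is
#' `q(s) = gamma + (1 - gamma) * Lambda(s)` with the logistic term
#' `Lambda(s) = 1 / (1 + exp((s - E*) / tau))`, where the effective extent
#' is `E* = E_m * kappa_inv^[invalid] * g(SOA) * rho_c^[high6]` and the SOA
#' gain ramps linearly from `soa_floor` to 1 at `soa_t_full_ms`:
#' `g(SOA) = min(1, soa_floor + (1 - soa_floor) * SOA / soa_t_full_ms)`.
#'
#' The defaults are calibrated so that a cohort of such observers shows
#' group-level behaviour typical of the task: horizontal extents wider than
#' vertical, analytic 75 % thresholds near 29 degrees under valid cueing,
#' and multiplicative shrinkage of roughly 14 % under invalid cues, 33 %
#' at a 50-ms cue-target interval and 29 % under the six-element alphabet.
#'
#' @param extent_h,extent_v,extent_d Meridian extents in degrees: the
#'   separation at which identification is halfway between floor and
#'   ceiling, for the horizontal, vertical and (pooled) diagonal meridians.
#' @param slope Logistic scale `tau` in degrees (> 0); smaller is steeper.
#' @param guess_rate Floor probability `gamma` in `[0, 1]`. The default 0.2
#'   equals uniform guessing over the five count responses (0-4); response
#'   simulation guesses uniformly over that alphabet, so only with
#'   `guess_rate = 0.2` does simulated accuracy equal `q` exactly.
#' @param validity_factor Multiplier `kappa_inv` in `(0, 1]` applied to the
#'   extent on invalid-cue trials.
#' @param soa_t_full_ms Cue-target blank interval (ms) at and beyond which
#'   the SOA gain is 1.
#' @param soa_floor Gain fraction in `(0, 1]` as SOA approaches 0.
#' @param complexity_factor Multiplier `rho_c` in `(0, 1]` applied under the
#'   six-element (`"high6"`) stimulus alphabet.
#' @param model `"attention_field"` (parallel, independent identification of
#'   both stimuli) or `"spotlight_shift"` (serial: the second stimulus is
#'   identified only if `target_ms - (shift_base_ms + shift_cost_ms_per_deg
#'   * separation) > 0`, else it is pure guessing).
#' @param shift_base_ms,shift_cost_ms_per_deg Spotlight-shift time budget:
#'   fixed engagement cost and per-degree travel cost.
#' @return An object of class `awt_observer`.
#' @examples
#' obs <- observer_params()
#' identification_probability(generate_session(seed = 1), obs)[1:3]
#' @export
observer_params <- function(extent_h = 36.5, extent_v = 30.5, extent_d = 33.5,
                            slope = 3, guess_rate = 0.2,
                            validity_factor = 0.88,
                            soa_t_full_ms = 200, soa_floor = 0.62,
                            complexity_factor = 0.75,
                            model = c("attention_field", "spotlight_shift"),
                            shift_base_ms = 50, shift_cost_ms_per_deg = 10) {
  model <- match.arg(model)
  assert_positive(slope, "slope")
  assert_scalar_prob(guess_rate, "guess_rate")
  for (nm in c("validity_factor", "soa_floor", "complexity_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1) {
      abort(sprintf("`%s` must lie in (0, 1].", nm))
    }
  }
  assert_positive(soa_t_full_ms, "soa_t_full_ms")
  if (min(extent_h, extent_v, extent_d) < 0) {
    abort("Extents must be non-negative degrees.")
  }
  structure(
    list(
      extent_h = extent_h, extent_v = extent_v, extent_d = extent_d,
      slope = slope, guess_rate = guess_rate,
      validity_factor = validity_factor,
      soa_t_full_ms = soa_t_full_ms, soa_floor = soa_floor,
      complexity_factor = complexity_factor,
      model = model,
      shift_base_ms = shift_base_ms,
      shift_cost_ms_per_deg = shift_cost_ms_per_deg
    ),
    class = "awt_observer"
  )
}

#' @export
print.awt_observer <- function(x, ...) {
  cat("<awt_observer>", x$model, "\n")
  cat(sprintf("  extents (H/V/D): %g / %g / %g deg, slope %g deg, guess %g\n",
              x$extent_h, x$extent_v, x$extent_d, x$slope, x$guess_rate))
  cat(sprintf("  validity %g, SOA ramp (floor %g, full at %g ms), complexity %g\n",
              x$validity_factor, x$soa_floor, x$soa_t_full_ms,
              x$complexity_factor))
  invisible(x)
}

# SOA gain g(SOA): linear ramp from soa_floor at 0 ms to 1 at soa_t_full_ms.
soa_gain <- function(params, soa_ms) {
  pmin(1, params$soa_floor + (1 - params$soa_floor) * soa_ms / params$soa_t_full_ms)
}

extent_for_meridian <- function(params, meridian) {
  cls <- meridian_class(meridian)
  unname(c(horizontal = params$extent_h, vertical = params$extent_v,
           diagonal = params$extent_d)[cls])
}

#' Effective attentional extent per trial
#'
#' Applies the multiplicative condition modifiers to the meridian extent:
#' `E* = E_m * kappa_inv^[invalid] * g(SOA) * rho_c^[high6]`.
#'
#' @param trials A trial tibble (see [generate_session()]).
#' @param params An [observer_params()] object.
#' @return Numeric vector of effective extents in degrees, one per trial.
#' @export
effective_extent <- function(trials, params) {
  e <- extent_for_meridian(params, trials$meridian)
  e <- e * ifelse(trials$cue_validity == "invalid", params$validity_factor, 1)
  e <- e * soa_gain(params, trials$soa_ms)
  e * ifelse(trials$complexity == "high6", params$complexity_factor, 1)
}

logistic_term <- function(s, extent, slope) {
  1 / (1 + exp((s - extent) / slope))
}

#' Single-stimulus identification probability
#'
#' The probability that the observer reports the correct target count for
#' one stimulus of a trial: `q = gamma + (1 - gamma) * Lambda(s)` with the
#' logistic term evaluated at the trial's separation and effective extent.
#' Deterministic given trial and parameters.
#'
#' @inheritParams effective_extent
#' @return Numeric vector `q` in `[gamma, 1]`, one per trial.
#' @export
identification_probability <- function(trials, params) {
  stopifnot(inherits(params, "awt_observer"))
  lam <- logistic_term(trials$separation_deg, effective_extent(trials, params),
                       params$slope)
  params$guess_rate + (1 - params$guess_rate) * lam
}

#' Pair-correct probability of a trial
#'
#' A trial is correct only when both stimulus counts are reported correctly.
#' Under the `attention_field` model the two identifications are independent
#' with the same `q`, so `P = q^2`. Under the `spotlight_shift` model the
#' first stimulus gets `q`; the second gets `q` only if the shift time
#' budget `target_ms - (shift_base_ms + shift_cost_ms_per_deg * s)` is
#' positive, and otherwise falls to the guessing floor `gamma`.
#'
#' @inheritParams effective_extent
#' @param target_ms Target presentation duration in ms (default 300).
#' @return Numeric vector of pair-correct probabilities in `[gamma^2, 1]`.
#' @export
pair_correct_probability <- function(trials, params, target_ms = 300) {
  q <- identification_probability(trials, params)
  if (params$model == "attention_field") {
    q * q
  } else {
    remaining <- target_ms -
      (params$shift_base_ms + params$shift_cost_ms_per_deg * trials$separation_deg)
    q * ifelse(remaining > 0, q, params$guess_rate)
  }
}

#' Analytic 75 % separation of an attention-field observer
#'
#' Closed-form separation at which the pair-correct probability reaches
#' `criterion`: solving `q(s)^2 = criterion` gives
#' `s* = E* + tau * log((1 - Lambda*) / Lambda*)` with
#' `Lambda* = (sqrt(criterion) - gamma) / (1 - gamma)`; at the default
#' guess rate this puts `s*` about `1.6 * tau` below the effective extent.
#' Only defined for the `attention_field` model.
#'
#' @param params An [observer_params()] object.
#' @param meridian Meridian identifier(s).
#' @param cue_validity `"valid"` or `"invalid"`.
#' @param soa_ms Cue-target blank interval in ms.
#' @param complexity `"basic4"` or `"high6"`.
#' @param criterion Pair-correct criterion (default 0.75).
#' @return Numeric vector of analytic threshold separations in degrees.
#' @export
analytic_threshold <- function(params, meridian = "horizontal",
                               cue_validity = "valid", soa_ms = 200,
                               complexity = "basic4", criterion = 0.75) {
  stopifnot(inherits(params, "awt_observer"))
  if (params$model != "attention_field") {
    abort("Closed-form thresholds exist only for the attention_field model.")
  }
  lam_star <- (sqrt(criterion) - params$guess_rate) / (1 - params$guess_rate)
  if (lam_star <= 0 || lam_star >= 1) {
    abort("Criterion unattainable for this guess rate.")
  }
  mock <- tibble(meridian = meridian, cue_validity = cue_validity,
                 soa_ms = soa_ms, complexity = complexity)
  e_star <- effective_extent(mock, params)
  e_star + params$slope * log((1 - lam_star) / lam_star)
}

#' Simulate an observer's responses to a trial schedule
#'
#' For each stimulus the observer identifies the true target count with the
#' logistic probability `Lambda` and otherwise guesses uniformly over the
#' five count responses (0-4), so the unconditional per-stimulus accuracy is
#' `gamma + (1 - gamma) * Lambda = q` when `gamma = 1/5`. Under the
#' `spotlight_shift` model the second stimulus is pure guessing whenever the
#' shift budget is exhausted. A trial is `correct` only when both reported
#' counts match the true counts.
#'
#' @param trials A trial tibble from [generate_session()].
#' @param params An [observer_params()] object.
#' @param seed Integer seed for the observer's response noise.
#' @param target_ms Target duration in ms for the spotlight time budget.
#' @return The trial tibble with `reported_count_a`, `reported_count_b` and
#'   `correct` columns appended.
#' @export
simulate_responses <- function(trials, params, seed = 1, target_ms = 300) {
  stopifnot(inherits(params, "awt_observer"))
  n <- nrow(trials)
  lam <- logistic_term(trials$separation_deg,
                       effective_extent(trials, params), params$slope)
  lam_b <- lam
  if (params$model == "spotlight_shift") {
    remaining <- target_ms -
      (params$shift_base_ms + params$shift_cost_ms_per_deg * trials$separation_deg)
    lam_b <- ifelse(remaining > 0, lam, 0)
  }
  out <- with_seed(seed, {
    id_a <- runif(n) < lam
    id_b <- runif(n) < lam_b
    guess_a <- resample(0:4, n, replace = TRUE)
    guess_b <- resample(0:4, n, replace = TRUE)
    list(
      a = ifelse(id_a, trials$target_count_a, guess_a),
      b = ifelse(id_b, trials$target_count_b, guess_b)
    )
  })
  trials$reported_count_a <- as.integer(out$a)
  trials$reported_count_b <- as.integer(out$b)
  trials$correct <- trials$reported_count_a == trials$target_count_a &
    trials$reported_count_b == trials$target_count_b
  trials
}

#' Draw a cohort of observers from a population
#'
#' Subject-level parameters are drawn from independent truncated normal
#' distributions around population means, emulating between-subject
#' variability in attentional extent. Factors and the slope are truncated to
#' their admissible ranges.
#'
#' @param n Number of observers.
#' @param seed Integer seed.
#' @param mean_params Population-mean parameters, an [observer_params()].
#' @param sd_extent Between-subject SD (degrees) shared by the three
#'   meridian extents. Default 4.
#' @param sd_slope Between-subject SD of the logistic slope. Default 0.3.
#' @return A named list of `awt_observer` objects (`"s01"`, `"s02"`, ...).
#' @export
observer_cohort <- function(n, seed = 1, mean_params = observer_params(),
                            sd_extent = 4, sd_slope = 0.3) {
  stopifnot(n >= 1)
  draws <- with_seed(seed, {
    list(
      eh = rtruncnorm(n, mean_params$extent_h, sd_extent, lower = 1),
      ev = rtruncnorm(n, mean_params$extent_v, sd_extent, lower = 1),
      ed = rtruncnorm(n, mean_params$extent_d, sd_extent, lower = 1),
      sl = rtruncnorm(n, mean_params$slope, sd_slope, lower = 0.5)
    )
  })
  obs <- lapply(seq_len(n), function(i) {
    p <- mean_params
    p$extent_h <- draws$eh[i]
    p$extent_v <- draws$ev[i]
    p$extent_d <- draws$ed[i]
    p$slope <- draws$sl[i]
    p
  })
  names(obs) <- sprintf("s%02d", seq_len(n))
  obs
}

# Truncated-normal sampler by rejection; fine for the mild truncations used.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

#' Simulate a cohort's trial records
#'
#' Gives every observer its own session schedule and response-noise stream
#' (both derived from the master seed) under a shared design configuration,
#' and stacks the resulting trial records in long format.
#'
#' @param observers Named list of [observer_params()] objects; names are the
#'   subject identifiers and must be unique.
#' @param config An [awt_config()].
#' @param seed Integer master seed.
#' @return A tibble of trial records with a `subject` column;
#'   `config$n_trials_per_session` rows per subject.
#' @examples
#' cohort <- observer_cohort(2, seed = 5)
#' records <- simulate_cohort(cohort, awt_config(), seed = 5)
#' nrow(records)  # 2 x 288
#' @export
simulate_cohort <- function(observers, config = awt_config(), seed = 1) {
  if (is.null(names(observers)) || anyDuplicated(names(observers))) {
    abort("`observers` must be a named list with unique subject identifiers.")
  }
  stopifnot(length(observers) >= 1)
  seeds <- child_seeds(seed, c("design", "noise"))
  design_seeds <- child_seeds(seeds[["design"]], names(observers))
  noise_seeds <- child_seeds(seeds[["noise"]], names(observers))
  target_ms <- config$timings_ms[["target"]]
  recs <- map(names(observers), function(id) {
    trials <- generate_session(config, seed = design_seeds[[id]])
    rec <- simulate_responses(trials, observers[[id]],
                              seed = noise_seeds[[id]], target_ms = target_ms)
    rec$subject <- id
    rec
  })
  out <- list_rbind(recs)
  relocate(out, "subject")
}
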