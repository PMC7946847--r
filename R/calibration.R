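# Fast cohort-level simulation for calibration studies (type-I error,
# power, qualitative-signature checks).
#
# Within one (subject, condition, meridian class, separation) cell every
# trial is an independent Bernoulli draw with the same pair-correct
# probability P, so the cell's correct count is exactly Binomial(n, P).
# Drawing the count directly reproduces the distribution of full per-trial
# simulation at a fraction of the cost; use simulate_cohort() whenever the
# individual trial records matter.

#' Condition tables for the fast simulation path
#'
#' One row per condition: a `condition` label plus the trial attributes
#' that drive the observer model (`cue_validity`, `soa_ms`, `complexity`).
#'
#' @param condition Condition labels.
#' @param cue_validity,soa_ms,complexity Recycled trial attributes.
#' @return A tibble describing the conditions.
#' @export
condition_table <- function(condition, cue_validity = "valid",
                            soa_ms = 200, complexity = "basic4") {
  tibble(condition = condition, cue_validity = cue_validity,
         soa_ms = soa_ms, complexity = complexity)
}

#' Simulate per-subject thresholds via binomial cell counts
#'
#' For every subject, condition and meridian class, draws the per-separation
#' correct counts as `Binomial(n_trials, P(s))` (the exact distribution of
#' per-trial simulation), scores the profile with the ascending criterion
#' rule and returns the threshold table. The diagonal class pools twice the
#' per-cell repetitions, as in the session design.
#'
#' @param observers Named list of [observer_params()] (one per subject).
#' @param conditions A [condition_table()].
#' @param separations Ascending separation grid in degrees.
#' @param reps_per_cell Trials per (raw meridian, separation) cell.
#' @param criterion Accuracy criterion, default 0.75.
#' @param seed Integer seed.
#' @return A tibble: `subject`, `condition`, `meridian_class`,
#'   `threshold_deg`, `censoring`.
#' @export
simulate_threshold_matrix <- function(observers, conditions,
                                      separations = seq(10, 45, by = 5),
                                      reps_per_cell = 9, criterion = 0.75,
                                      seed = 1) {
  classes <- c("horizontal", "vertical", "diagonal")
  n_trials <- c(horizontal = reps_per_cell, vertical = reps_per_cell,
                diagonal = 2 * reps_per_cell)
  ns <- length(separations)
  ids <- names(observers)
  nrow_out <- length(ids) * nrow(conditions) * length(classes)
  sub_v <- character(nrow_out); con_v <- character(nrow_out)
  cls_v <- character(nrow_out); thr_v <- numeric(nrow_out)
  cen_v <- character(nrow_out)
  with_seed(seed, {
    r <- 0L
    for (id in ids) {
      p <- observers[[id]]
      ext <- c(horizontal = p$extent_h, vertical = p$extent_v,
               diagonal = p$extent_d)
      for (ci in seq_len(nrow(conditions))) {
        cond <- conditions[ci, ]
        gain <- (if (cond$cue_validity == "invalid") p$validity_factor else 1) *
          soa_gain(p, cond$soa_ms) *
          (if (cond$complexity == "high6") p$complexity_factor else 1)
        for (cl in classes) {
          q <- p$guess_rate + (1 - p$guess_rate) *
            logistic_term(separations, ext[[cl]] * gain, p$slope)
          prob <- if (p$model == "attention_field") {
            q * q
          } else {
            remaining <- 300 - (p$shift_base_ms +
                                  p$shift_cost_ms_per_deg * separations)
            q * ifelse(remaining > 0, q, p$guess_rate)
          }
          acc <- rbinom(ns, n_trials[[cl]], prob) / n_trials[[cl]]
          thr <- threshold_scan(acc, separations, criterion)
          r <- r + 1L
          sub_v[r] <- id; con_v[r] <- cond$condition; cls_v[r] <- cl
          thr_v[r] <- thr$threshold_deg; cen_v[r] <- thr$censoring
        }
      }
    }
  })
  tibble(subject = sub_v, condition = con_v, meridian_class = cls_v,
         threshold_deg = thr_v, censoring = cen_v)
}

#' Condition-effect p-values over many simulated cohorts
#'
#' Repeatedly draws a cohort of observers, simulates their thresholds in
#' every condition through the binomial fast path, and runs the
#' condition x meridian repeated-measures ANOVA, collecting the
#' condition-main-effect p-value per cohort (the Greenhouse-Geisser
#' corrected value whenever Mauchly's test rejects, matching the reporting
#' rule). With identical trial attributes in every condition this
#' estimates the type-I error rate at a given alpha; with differing
#' attributes it estimates power.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param conditions A [condition_table()]; each subject serves in all
#'   conditions (fully within design).
#' @param n_subjects Cohort size, default 20.
#' @param mean_params Population-mean [observer_params()].
#' @param sd_extent,sd_slope Between-subject SDs (see [observer_cohort()]).
#' @param separations,reps_per_cell Design grid.
#' @param seed Integer master seed.
#' @return A tibble with one row per cohort: `cohort`, `p_condition`.
#' @export
simulate_condition_pvalues <- function(n_cohorts, conditions,
                                       n_subjects = 20,
                                       mean_params = observer_params(),
                                       sd_extent = 4, sd_slope = 0.3,
                                       separations = seq(10, 45, by = 5),
                                       reps_per_cell = 9, seed = 1) {
  seeds <- child_seeds(seed, c("cohort", "trials"))
  cohort_seeds <- with_seed(seeds[["cohort"]],
                            sample.int(.Machine$integer.max - 1L, n_cohorts))
  trial_seeds <- with_seed(seeds[["trials"]],
                           sample.int(.Machine$integer.max - 1L, n_cohorts))
  pvals <- vapply(seq_len(n_cohorts), function(i) {
    obs <- observer_cohort(n_subjects, seed = cohort_seeds[i],
                           mean_params = mean_params,
                           sd_extent = sd_extent, sd_slope = sd_slope)
    thr <- simulate_threshold_matrix(obs, conditions, separations,
                                     reps_per_cell, seed = trial_seeds[i])
    fit <- rm_anova(thr, dv = "threshold_deg", subject = "subject",
                    within = c("condition", "meridian_class"))
    fit$effects$p_reported[fit$effects$effect == "condition"]
  }, numeric(1))
  tibble(cohort = seq_len(n_cohorts), p_condition = pvals)
}

#' Type-I error of the condition main effect under the null
#'
#' Simulates cohorts in which every condition has identical trial
#' attributes (so the condition effect is truly null) and reports the
#' rejection rate of the condition main effect at `alpha`.
#'
#' @inheritParams simulate_condition_pvalues
#' @param alpha Nominal level, default 0.05.
#' @return A one-row tibble: `n_cohorts`, `alpha`, `rejections`,
#'   `type1_rate`.
#' @export
simulate_null_type1 <- function(n_cohorts = 1000, n_subjects = 20,
                                mean_params = observer_params(),
                                sd_extent = 4, sd_slope = 0.3,
                                alpha = 0.05, seed = 1) {
  conditions <- condition_table(c("c1", "c2"))
  res <- simulate_condition_pvalues(
    n_cohorts, conditions, n_subjects = n_subjects,
    mean_params = mean_params, sd_extent = sd_extent, sd_slope = sd_slope,
    seed = seed
  )
  tibble(
    n_cohorts = n_cohorts, alpha = alpha,
    rejections = sum(res$p_condition < alpha),
    type1_rate = mean(res$p_condition < alpha)
  )
}
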