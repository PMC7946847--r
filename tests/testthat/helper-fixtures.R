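# Shared fixtures: tiny designs, deterministic observers, mock trial tables.

tiny_config <- function(...) {
  awt_config(separations_deg = c(10, 20, 30), meridians = c("horizontal", "vertical"),
             reps_per_cell = 2, ...)
}

# a trial table carrying just the columns the observer model reads
mock_trials <- function(separation_deg, meridian = "horizontal",
                        cue_validity = "valid", soa_ms = 200,
                        complexity = "basic4") {
  tibble::tibble(
    meridian = meridian, separation_deg = separation_deg,
    cue_validity = cue_validity, soa_ms = soa_ms, complexity = complexity
  )
}

# balanced random threshold-like data for ANOVA tests
random_rm_data <- function(n_subjects, a_levels, b_levels, seed,
                           mean = 25, sd = 5) {
  withr::with_seed(seed, {
    d <- tidyr::expand_grid(
      subject = sprintf("s%02d", seq_len(n_subjects)),
      A = a_levels, B = b_levels
    )
    d$y <- stats::rnorm(nrow(d), mean, sd)
    d
  })
}

# independent oracle: classical aov() with Error() strata
aov_oracle <- function(d) {
  dd <- transform(as.data.frame(d), subject = factor(subject),
                  A = factor(A), B = factor(B))
  s <- summary(stats::aov(y ~ A * B + Error(subject / (A * B)), data = dd))
  get_f <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(A = get_f("Error: subject:A", "A"),
    B = get_f("Error: subject:B", "B"),
    AB = get_f("Error: subject:A:B", "A:B"))
}
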