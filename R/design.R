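# Trial-design generation for the Attention-Window Task (AWT).
#
# A session is a stratified factorial schedule: every (meridian, separation)
# cell appears exactly `reps_per_cell` times; randomisation affects trial
# order, cue-validity draws, invalid-cue placement and stimulus contents only.

#' Meridian angles (degrees counterclockwise from the positive x axis)
#'
#' The four meridians of the task are the horizontal axis, the vertical axis
#' and the two diagonals, separated by 45 degrees of rotation. The stimulus
#' pair sits at polar radii of plus/minus half the separation along the
#' meridian.
#'
#' @return Named numeric vector of meridian angles in degrees.
#' @export
meridian_angles <- function() {
  c(horizontal = 0, diagonal1 = 45, vertical = 90, diagonal2 = 135)
}

#' Collapse raw meridians into analysis classes
#'
#' The two diagonal meridians are treated as one "diagonal" level throughout
#' the analysis, so the meridian factor has three levels (horizontal,
#' vertical, diagonal).
#'
#' @param meridian Character vector of raw meridian identifiers.
#' @return Character vector of meridian classes.
#' @export
meridian_class <- function(meridian) {
  ifelse(meridian %in% c("diagonal1", "diagonal2"), "diagonal", meridian)
}

# Element codes: shape (T triangle, C circle, S square) + shade (l light,
# d dark). The target element is the light-gray triangle "Tl".
target_element <- function() "Tl"

nontarget_elements <- function(complexity) {
  switch(complexity,
    basic4 = c("Td", "Cl", "Cd"),
    high6  = c("Td", "Cl", "Cd", "Sl", "Sd"),
    abort("`complexity` must be \"basic4\" or \"high6\".")
  )
}

#' Session design configuration
#'
#' Describes one AWT session: the separation grid, the meridians, the number
#' of repetitions per (meridian, separation) cell, the cue-validity mixture,
#' the cue-to-target blank interval and the stimulus complexity. Under the
#' defaults the design is the basic task: 8 separations x 4 meridians x 9
#' repetitions = 288 trials, all cues valid.
#'
#' `soa_ms` is the blank interval between cue offset and target onset (200 ms
#' in the basic task); the onset-to-onset asynchrony is `soa_ms +
#' timings_ms["cue"]` and is carried in the configuration as
#' `soa_onset_to_onset_ms`.
#'
#' @param separations_deg Strictly increasing separations in degrees of
#'   visual angle between the two stimuli. Default `seq(10, 45, by = 5)`.
#' @param meridians Meridian identifiers. Default the four task meridians.
#' @param reps_per_cell Trials per (meridian, separation) cell. Default 9.
#' @param cue_valid_fraction Probability that a trial carries a valid cue
#'   (cues at the upcoming target positions). 1 in the basic task, 0.8 in the
#'   modified task.
#' @param soa_ms Cue-offset-to-target-onset blank interval in ms (>= 0).
#' @param complexity `"basic4"` (circles and triangles, light or dark: four
#'   element types) or `"high6"` (adds squares: six element types).
#' @param timings_ms Named vector with `fixation`, `cue` and `target`
#'   durations in ms.
#' @return An object of class `awt_config`.
#' @examples
#' cfg <- awt_config()
#' cfg$n_trials_per_session
#' @export
awt_config <- function(separations_deg = seq(10, 45, by = 5),
                       meridians = names(meridian_angles()),
                       reps_per_cell = 9,
                       cue_valid_fraction = 1,
                       soa_ms = 200,
                       complexity = c("basic4", "high6"),
                       timings_ms = c(fixation = 1000, cue = 200, target = 300)) {
  complexity <- match.arg(complexity)
  if (length(separations_deg) == 0 || length(meridians) == 0) {
    abort("`separations_deg` and `meridians` must be non-empty.")
  }
  if (any(diff(separations_deg) <= 0)) {
    abort("`separations_deg` must be strictly increasing.")
  }
  if (anyDuplicated(meridians)) abort("`meridians` must be unique.")
  if (!is.numeric(reps_per_cell) || reps_per_cell < 1 ||
      reps_per_cell != round(reps_per_cell)) {
    abort("`reps_per_cell` must be a positive integer.")
  }
  assert_scalar_prob(cue_valid_fraction, "cue_valid_fraction")
  if (!is.numeric(soa_ms) || length(soa_ms) != 1 || soa_ms < 0) {
    abort("`soa_ms` must be a single non-negative duration in ms.")
  }
  stopifnot(all(c("fixation", "cue", "target") %in% names(timings_ms)))
  cfg <- structure(
    list(
      separations_deg = as.numeric(separations_deg),
      meridians = as.character(meridians),
      reps_per_cell = as.integer(reps_per_cell),
      cue_valid_fraction = cue_valid_fraction,
      soa_ms = as.numeric(soa_ms),
      complexity = complexity,
      timings_ms = timings_ms,
      soa_onset_to_onset_ms = as.numeric(soa_ms + timings_ms[["cue"]]),
      n_trials_per_session = length(separations_deg) * length(meridians) *
        as.integer(reps_per_cell)
    ),
    class = "awt_config"
  )
  cfg
}

#' @export
print.awt_config <- function(x, ...) {
  cat("<awt_config>\n")
  cat("  separations:", paste(x$separations_deg, collapse = ", "), "deg\n")
  cat("  meridians:  ", paste(x$meridians, collapse = ", "), "\n")
  cat(sprintf("  reps/cell: %d  trials/session: %d\n",
              x$reps_per_cell, x$n_trials_per_session))
  cat(sprintf("  cue validity: %.2f  SOA (blank): %g ms  complexity: %s\n",
              x$cue_valid_fraction, x$soa_ms, x$complexity))
  invisible(x)
}

#' Generate random stimulus groups
#'
#' Each stimulus group comprises four elements. The number of target elements
#' (light-gray triangles) is drawn uniformly from 0 to 4, so each count has a
#' 20 % long-run probability; the remaining elements are drawn uniformly from
#' the non-target alphabet of the chosen complexity, and element order is
#' randomly permuted.
#'
#' @param n Number of stimulus groups to draw.
#' @param complexity `"basic4"` or `"high6"`.
#' @return A tibble with one row per group: `stimulus` (four comma-separated
#'   element codes, e.g. `"Tl,Cd,Cl,Td"`) and `target_count` (0-4).
#' @examples
#' set.seed(1)
#' generate_stimuli(3)
#' @export
generate_stimuli <- function(n, complexity = "basic4") {
  pool <- nontarget_elements(complexity)
  target_count <- sample(0:4, n, replace = TRUE)
  n_fill <- 4L * n - sum(target_count)
  fill <- sample(pool, n_fill, replace = TRUE)
  elems <- character(4L * n)
  gid <- rep(seq_len(n), each = 4L)
  is_target <- sequence(rep(4L, n)) <= target_count[gid]
  elems[is_target] <- target_element()
  elems[!is_target] <- fill
  # random within-group permutation: sort positions by (group, uniform key)
  elems <- elems[order(gid, runif(4L * n))]
  m <- matrix(elems, nrow = 4L)
  tibble(
    stimulus = paste(m[1, ], m[2, ], m[3, ], m[4, ], sep = ","),
    target_count = as.integer(target_count)
  )
}

#' Count target elements in an encoded stimulus
#'
#' @param stimulus Character vector of comma-separated element codes.
#' @return Integer vector: the number of light-gray triangles (`"Tl"`).
#' @export
count_targets <- function(stimulus) {
  vapply(strsplit(stimulus, ",", fixed = TRUE),
         function(e) sum(e == target_element()), integer(1))
}

#' Generate one session's trial schedule
#'
#' Builds the stratified factorial schedule for one session: every
#' (meridian, separation) cell appears exactly `reps_per_cell` times, trial
#' order is randomly permuted, cue validity is an independent Bernoulli draw
#' per trial with probability `cue_valid_fraction`, invalid cues are placed
#' on a random non-target meridian at a random separation, and stimulus
#' contents are drawn per [generate_stimuli()]. All randomness derives from
#' `seed` through independent child streams (order, validity, cue placement,
#' stimuli), so components are reproducible in isolation.
#'
#' @param config An [awt_config()].
#' @param seed Integer master seed.
#' @return A tibble with one row per trial: `trial_id`, `meridian`,
#'   `separation_deg`, `cue_validity` (`"valid"`/`"invalid"`),
#'   `cue_meridian`, `cue_separation_deg`, `soa_ms`, `complexity`,
#'   `stim_a`, `stim_b`, `target_count_a`, `target_count_b`. The stimuli sit
#'   at polar radius `separation_deg / 2` on either side of fixation along
#'   the meridian; valid cues share the stimulus positions.
#' @examples
#' trials <- generate_session(awt_config(), seed = 1)
#' nrow(trials)  # 288
#' @export
generate_session <- function(config = awt_config(), seed = 1) {
  stopifnot(inherits(config, "awt_config"))
  seeds <- child_seeds(seed, c("order", "validity", "cue", "stimuli"))

  cells <- expand_grid(
    meridian = config$meridians,
    separation_deg = config$separations_deg,
    rep = seq_len(config$reps_per_cell)
  )
  n <- nrow(cells)
  ord <- with_seed(seeds[["order"]], sample.int(n))
  trials <- cells[ord, c("meridian", "separation_deg")]

  valid <- with_seed(seeds[["validity"]],
                     runif(n) < config$cue_valid_fraction)
  trials$cue_validity <- ifelse(valid, "valid", "invalid")
  trials$cue_meridian <- trials$meridian
  trials$cue_separation_deg <- trials$separation_deg
  n_inv <- sum(!valid)
  if (n_inv > 0) {
    if (length(config$meridians) < 2) {
      abort("Invalid cues require at least two meridians in the design.")
    }
    placement <- with_seed(seeds[["cue"]], {
      cue_mer <- vapply(trials$meridian[!valid], function(m) {
        sample(setdiff(config$meridians, m), 1)
      }, character(1))
      cue_sep <- resample(config$separations_deg, n_inv, replace = TRUE)
      list(mer = cue_mer, sep = cue_sep)
    })
    trials$cue_meridian[!valid] <- placement$mer
    trials$cue_separation_deg[!valid] <- placement$sep
  }

  stim <- with_seed(seeds[["stimuli"]],
                    generate_stimuli(2L * n, config$complexity))
  a <- stim[seq_len(n), ]
  b <- stim[n + seq_len(n), ]

  out <- tibble(
    trial_id = seq_len(n),
    meridian = trials$meridian,
    separation_deg = trials$separation_deg,
    cue_validity = trials$cue_validity,
    cue_meridian = trials$cue_meridian,
    cue_separation_deg = trials$cue_separation_deg,
    soa_ms = config$soa_ms,
    complexity = config$complexity,
    stim_a = a$stimulus,
    stim_b = b$stimulus,
    target_count_a = a$target_count,
    target_count_b = b$target_count
  )
  attr(out, "awt_config") <- config
  attr(out, "seed") <- seed
  out
}

#' Reassign the cue of an invalid trial
#'
#' Places the cue pair of an invalid-cue trial on a uniformly chosen
#' non-target meridian at a uniformly chosen separation from the design
#' grid. Both cues share one meridian, mirroring the symmetric valid-cue
#' geometry; the target positions are untouched.
#'
#' @param trial A one-row trial tibble with `cue_validity == "invalid"`.
#' @param config The session's [awt_config()].
#' @return The trial with `cue_meridian` and `cue_separation_deg` redrawn.
#' @export
assign_invalid_cue <- function(trial, config = awt_config()) {
  stopifnot(nrow(trial) == 1)
  if (trial$cue_validity != "invalid") {
    abort("`assign_invalid_cue()` applies only to invalid-cue trials.")
  }
  candidates <- setdiff(config$meridians, trial$meridian)
  if (length(candidates) == 0) {
    abort("No non-target meridian exists in this design.")
  }
  trial$cue_meridian <- resample(candidates, 1)
  trial$cue_separation_deg <- resample(config$separations_deg, 1)
  trial
}
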