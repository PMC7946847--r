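# Inferential battery: two-way repeated-measures ANOVA with sphericity
# diagnostics and Greenhouse-Geisser (GG) correction, partial eta squared,
# Bonferroni-corrected pairwise comparisons, percent-reduction summaries.

orthonormal_contrasts <- function(p) {
  # any orthonormal basis of the (p-1)-dim contrast space; W and epsilon are
  # invariant to the choice
  h <- stats::contr.helmert(p)
  sweep(h, 2, sqrt(colSums(h^2)), "/")
}

#' Mauchly's sphericity test and Greenhouse-Geisser epsilon
#'
#' Operates on the covariance matrix of orthonormally contrasted
#' within-subject scores (k = levels - 1 contrasts, n subjects). Mauchly's
#' `W = det(S) / (tr(S)/k)^k`; the chi-square approximation uses the
#' standard scaling `-(n-1) * (1 - (2k^2 + k + 2) / (6k(n-1))) * log(W)` on
#' `k(k+1)/2 - 1` degrees of freedom. The Greenhouse-Geisser estimate is
#' `epsilon = (sum lambda)^2 / (k * sum lambda^2)` over the eigenvalues of
#' `S`, bounded in `[1/k, 1]`.
#'
#' @param S Covariance matrix of the contrasted scores (k x k).
#' @param n Number of subjects.
#' @return A one-row tibble: `mauchly_w`, `chisq`, `df`, `p_mauchly`,
#'   `epsilon`. For `k = 1` the test is trivial (`W = 1`, `epsilon = 1`).
#' @export
mauchly_gg <- function(S, n) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k == 1) {
    return(tibble(mauchly_w = 1, chisq = 0, df = 0, p_mauchly = NA_real_,
                  epsilon = 1))
  }
  if (n <= k) {
    warn(sprintf(
      "Only %d subjects for %d contrasts; the sphericity test is unreliable.",
      n, k))
  }
  lambda <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  detS <- prod(lambda)
  if (detS <= 0) {
    abort("Contrast covariance is singular; Mauchly's W is degenerate (0).")
  }
  W <- detS / (sum(lambda) / k)^k
  scale <- 1 - (2 * k^2 + k + 2) / (6 * k * (n - 1))
  chisq <- -(n - 1) * scale * log(W)
  df <- k * (k + 1) / 2 - 1
  eps <- sum(lambda)^2 / (k * sum(lambda^2))
  tibble(
    mauchly_w = W, chisq = chisq, df = df,
    p_mauchly = pchisq(chisq, df, lower.tail = FALSE),
    epsilon = min(1, max(1 / k, eps))
  )
}

# subjects x cells matrix; for two factors the cells are in A-major order
# (first factor slowest), matching kronecker(contrasts_A, contrasts_B)
cell_matrix <- function(data, dv, subject, factors) {
  lv <- lapply(factors, function(f) sort(unique(data[[f]])))
  grid <- expand.grid(rev(lv), stringsAsFactors = FALSE)[rev(seq_along(lv))]
  labels <- do.call(paste, c(unname(grid), sep = ":"))
  key <- do.call(paste, c(lapply(factors, function(f) data[[f]]), sep = ":"))
  wide <- data |>
    mutate(.cell = key) |>
    select(all_of(c(subject, ".cell", dv))) |>
    pivot_wider(names_from = ".cell", values_from = all_of(dv))
  m <- as.matrix(wide[, labels, drop = FALSE])
  rownames(m) <- wide[[subject]]
  m
}

#' Two-way repeated-measures ANOVA
#'
#' Fits the classical fully-within two-factor ANOVA on a complete balanced
#' subject x A x B table: sums of squares are partitioned into subject, A,
#' B, A x B and their subject-interaction error strata, each effect is
#' tested against its own error stratum, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error)`. For every effect with two or more
#' numerator degrees of freedom, Mauchly's sphericity test and the
#' Greenhouse-Geisser epsilon are computed from the orthonormal contrast
#' covariance of that effect's within-subject scores; following common
#' reporting practice the GG-corrected degrees of freedom and p-value are
#' adopted as `p_reported` when Mauchly's p < 0.05 (both corrected and
#' uncorrected values are always returned).
#'
#' @param data Long tibble with one row per subject x cell.
#' @param dv Name of the dependent-variable column (e.g. `"threshold_deg"`).
#' @param subject Name of the subject-identifier column.
#' @param within Character vector naming the two within-subject factor
#'   columns, e.g. `c("condition", "meridian_class")`.
#' @return An object of class `awt_anova`; see [tidy.awt_anova()].
#' @examples
#' d <- tidyr::expand_grid(subject = paste0("s", 1:6),
#'                         condition = c("a", "b"),
#'                         meridian = c("horizontal", "vertical", "diagonal"))
#' d$y <- stats::rnorm(nrow(d), mean = 25)
#' rm_anova(d, dv = "y", subject = "subject",
#'          within = c("condition", "meridian"))
#' @export
rm_anova <- function(data, dv, subject = "subject", within) {
  stopifnot(length(within) == 2, all(c(dv, subject, within) %in% names(data)))
  a_lev <- unique(data[[within[1]]])
  b_lev <- unique(data[[within[2]]])
  subj <- unique(data[[subject]])
  n <- length(subj); a <- length(a_lev); b <- length(b_lev)
  if (n < 2) abort("A repeated-measures ANOVA needs at least 2 subjects.")
  counts <- table(data[[subject]], data[[within[1]]], data[[within[2]]])
  if (any(counts != 1)) {
    abort("Design must be complete and balanced: one value per subject x cell.")
  }

  y <- data[[dv]]
  m <- mean(y)
  ms <- tapply(y, data[[subject]], mean)
  mi <- tapply(y, data[[within[1]]], mean)
  mj <- tapply(y, data[[within[2]]], mean)
  mij <- tapply(y, list(data[[within[1]]], data[[within[2]]]), mean)
  msi <- tapply(y, list(data[[subject]], data[[within[1]]]), mean)
  msj <- tapply(y, list(data[[subject]], data[[within[2]]]), mean)

  ss_total <- sum((y - m)^2)
  ss_s <- a * b * sum((ms - m)^2)
  ss_a <- n * b * sum((mi - m)^2)
  ss_b <- n * a * sum((mj - m)^2)
  ss_ab <- n * sum((mij - outer(mi - m, mj - m, "+") - m)^2)
  ss_as <- b * sum((msi - outer(ms - m, mi - m, "+") - m)^2)
  ss_bs <- a * sum((msj - outer(ms - m, mj - m, "+") - m)^2)
  ss_abs <- ss_total - ss_s - ss_a - ss_b - ss_ab - ss_as - ss_bs

  eff <- tibble(
    effect = c(within[1], within[2], paste(within, collapse = ":")),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    df_num = c(a - 1, b - 1, (a - 1) * (b - 1))
  )
  eff$df_den <- eff$df_num * (n - 1)
  # a zero-SS effect is a null effect (F = 0), not 0/0
  eff$statistic <- ifelse(eff$ss == 0, 0,
                          (eff$ss / eff$df_num) / (eff$ss_error / eff$df_den))
  eff$p_value <- pf(eff$statistic, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$partial_eta_sq <- ifelse(eff$ss + eff$ss_error == 0, NA_real_,
                               eff$ss / (eff$ss + eff$ss_error))

  # sphericity per effect from the orthonormal contrast covariance of the
  # effect-specific within-subject scores
  ca <- orthonormal_contrasts(a)
  cb <- orthonormal_contrasts(b)
  marginal <- function(f) {
    data |>
      group_by(across(all_of(c(subject, f)))) |>
      summarise("{dv}" := mean(.data[[dv]]), .groups = "drop")
  }
  ya <- cell_matrix(marginal(within[1]), dv, subject, within[1])
  yb <- cell_matrix(marginal(within[2]), dv, subject, within[2])
  yab <- cell_matrix(data, dv, subject, within)
  cab <- kronecker(ca, cb)
  # degenerate data (e.g. fully censored thresholds) can make the contrast
  # covariance singular; report the uncorrected test rather than fail
  safe_mauchly <- function(S, n) {
    tryCatch(mauchly_gg(S, n), error = function(e) {
      k <- nrow(as.matrix(S))
      tibble(mauchly_w = NA_real_, chisq = NA_real_,
             df = k * (k + 1) / 2 - 1, p_mauchly = NA_real_, epsilon = 1)
    })
  }
  sph <- list(
    safe_mauchly(stats::cov(ya %*% ca), n),
    safe_mauchly(stats::cov(yb %*% cb), n),
    safe_mauchly(stats::cov(yab %*% cab), n)
  ) |> list_rbind()

  eff <- bind_cols(eff, sph)
  eff$df_num_gg <- eff$df_num * eff$epsilon
  eff$df_den_gg <- eff$df_den * eff$epsilon
  eff$p_gg <- pf(eff$statistic, eff$df_num_gg, eff$df_den_gg,
                 lower.tail = FALSE)
  eff$sphericity_violated <- !is.na(eff$p_mauchly) & eff$p_mauchly < 0.05
  eff$p_reported <- ifelse(eff$sphericity_violated, eff$p_gg, eff$p_value)

  structure(
    list(
      effects = eff,
      n_subjects = n,
      within = within,
      dv = dv,
      ss_subject = ss_s,
      ss_total = ss_total
    ),
    class = "awt_anova"
  )
}

#' @describeIn rm_anova Effect table, one row per effect (A, B, A:B) with
#'   `df_num`, `df_den`, `statistic` (F), `p_value`, `partial_eta_sq`,
#'   sphericity diagnostics (`mauchly_w`, `chisq`, `p_mauchly`, `epsilon`)
#'   and GG-corrected values.
#' @param x An `awt_anova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.awt_anova <- function(x, ...) {
  x$effects
}

#' @describeIn rm_anova One-row model summary.
#' @exportS3Method generics::glance
glance.awt_anova <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    ss_total = x$ss_total,
    ss_subject = x$ss_subject,
    n_effects = nrow(x$effects)
  )
}

#' @export
print.awt_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA on %s (%d subjects)\n",
              x$dv, x$n_subjects))
  for (i in seq_len(nrow(x$effects))) {
    e <- x$effects[i, ]
    if (e$sphericity_violated) {
      cat(sprintf(
        "  %s: F(%.3f, %.3f) = %.3f, p = %.3f, etap2 = %.3f, GG eps = %.3f (Mauchly p = %.3f)\n",
        e$effect, e$df_num_gg, e$df_den_gg, e$statistic, e$p_gg,
        e$partial_eta_sq, e$epsilon, e$p_mauchly))
    } else {
      cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.3f, etap2 = %.3f\n",
                  e$effect, e$df_num, e$df_den, e$statistic, e$p_value,
                  e$partial_eta_sq))
    }
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise comparisons for one within factor
#'
#' Collapses the data to subject-level marginal means of the chosen factor
#' (averaging across the other factors), runs paired t-tests on every level
#' pair, and applies the Bonferroni criterion: a comparison is significant
#' when its raw p-value is below `alpha / n_comparisons` (for three levels,
#' 0.05 / 3 = 0.017).
#'
#' @param data Long tibble with one or more rows per subject x level.
#' @param dv Dependent-variable column name.
#' @param factor Column name of the factor to compare.
#' @param subject Subject-identifier column name.
#' @param alpha Family-wise error rate, default 0.05.
#' @return A tibble with one row per level pair: `level_1`, `level_2`,
#'   `mean_diff`, `statistic`, `df`, `p_value`, `p_bonferroni`,
#'   `alpha_adjusted`, `significant`.
#' @export
pairwise_bonferroni <- function(data, dv, factor, subject = "subject",
                                alpha = 0.05) {
  means <- data |>
    group_by(across(all_of(c(subject, factor)))) |>
    summarise(.m = mean(.data[[dv]]), .groups = "drop")
  wide <- pivot_wider(means, names_from = all_of(factor), values_from = ".m")
  levels <- setdiff(names(wide), subject)
  pairs <- utils::combn(levels, 2, simplify = FALSE)
  k <- length(pairs)
  out <- map(pairs, function(p) {
    d <- wide[[p[1]]] - wide[[p[2]]]
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    tstat <- if (se == 0) 0 else mean(d) / se
    pval <- if (se == 0 && mean(d) == 0) 1 else 2 * pt(abs(tstat), n - 1, lower.tail = FALSE)
    tibble(level_1 = p[1], level_2 = p[2], mean_diff = mean(d),
           statistic = tstat, df = n - 1, p_value = pval)
  }) |> list_rbind()
  out$p_bonferroni <- pmin(1, out$p_value * k)
  out$alpha_adjusted <- alpha / k
  out$significant <- out$p_value < out$alpha_adjusted
  out
}

#' Percent reduction between two condition means
#'
#' Summarises an effect as the percentage by which a comparison mean falls
#' short of a reference mean: `100 * (mean_ref - mean_cmp) / mean_ref`.
#'
#' @param mean_ref Reference condition mean (must be positive), degrees.
#' @param mean_cmp Comparison condition mean, degrees.
#' @return A one-row tibble: `mean_ref`, `mean_cmp`, `percent` (raw) and
#'   `percent_rounded` (nearest integer).
#' @examples
#' percent_reduction(28.83, 24.75)  # 14 %
#' @export
percent_reduction <- function(mean_ref, mean_cmp) {
  if (!is.numeric(mean_ref) || mean_ref <= 0) {
    abort("`mean_ref` must be positive.")
  }
  pct <- 100 * (mean_ref - mean_cmp) / mean_ref
  tibble(mean_ref = mean_ref, mean_cmp = mean_cmp,
         percent = pct, percent_rounded = round(pct))
}
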