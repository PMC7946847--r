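# Repeated-measures ANOVA, sphericity, pairwise comparisons, reductions.

test_that("a 20-subject 2x3 design has the classical df structure", {
  d <- random_rm_data(20, c("basic", "modified"),
                      c("horizontal", "vertical", "diagonal"), seed = 1)
  fit <- rm_anova(d, dv = "y", subject = "subject", within = c("A", "B"))
  eff <- generics::tidy(fit)
  expect_equal(eff$df_num, c(1, 2, 2))
  expect_equal(eff$df_den, c(19, 38, 38))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("a null within-subject factor yields zero sum of squares", {
  d <- random_rm_data(8, "a1", c("b1", "b2", "b3"), seed = 3)
  # duplicate the B profile across two A levels within subject
  d2 <- dplyr::bind_rows(dplyr::mutate(d, A = "a1"),
                         dplyr::mutate(d, A = "a2"))
  fit <- rm_anova(d2, dv = "y", subject = "subject", within = c("A", "B"))
  eff <- generics::tidy(fit)
  expect_equal(eff$ss[eff$effect == "A"], 0)
  expect_equal(eff$statistic[eff$effect == "A"], 0)
})

test_that("F ratios match the aov() error-stratum oracle across shapes", {
  shapes <- list(
    list(n = 5, a = c("x", "y"), b = c("p", "q", "r")),
    list(n = 7, a = c("x", "y", "z"), b = c("p", "q", "r")),
    list(n = 6, a = c("x", "y"), b = c("p", "q", "r", "s"))
  )
  for (i in seq_along(shapes)) {
    sh <- shapes[[i]]
    d <- random_rm_data(sh$n, sh$a, sh$b, seed = 100 + i)
    fit <- rm_anova(d, dv = "y", subject = "subject", within = c("A", "B"))
    oracle <- aov_oracle(d)
    expect_equal(generics::tidy(fit)$statistic, unname(oracle),
                 tolerance = 1e-10)
  }
})

test_that("sums of squares partition the total", {
  for (i in 1:10) {
    d <- random_rm_data(6, c("x", "y"), c("p", "q", "r"), seed = 200 + i)
    fit <- rm_anova(d, dv = "y", subject = "subject", within = c("A", "B"))
    eff <- generics::tidy(fit)
    expect_equal(sum(eff$ss) + sum(eff$ss_error) + fit$ss_subject,
                 fit$ss_total, tolerance = 1e-9)
  }
})

test_that("incomplete or single-subject designs are rejected", {
  d <- random_rm_data(5, c("x", "y"), c("p", "q"), seed = 4)
  expect_error(rm_anova(d[-1, ], dv = "y", subject = "subject",
                        within = c("A", "B")), "complete")
  d1 <- random_rm_data(1, c("x", "y"), c("p", "q"), seed = 4)
  expect_error(rm_anova(d1, dv = "y", subject = "subject",
                        within = c("A", "B")), "2 subjects")
})

test_that("mauchly_gg matches hand formulas and the base-R oracle", {
  # spherical covariance: W = 1, chi-square 0, epsilon 1
  sph <- mauchly_gg(diag(2) * 3, n = 12)
  expect_equal(sph$mauchly_w, 1)
  expect_equal(sph$chisq, 0)
  expect_equal(sph$epsilon, 1)
  # hand evaluation of epsilon for contrast eigenvalues (4, 1)
  s <- diag(c(4, 1))
  expect_equal(mauchly_gg(s, n = 10)$epsilon, 25 / 34)
  # two-level factor is trivially spherical
  expect_equal(mauchly_gg(matrix(2), n = 10)$epsilon, 1)
  # singular covariance is an explicit error
  expect_error(mauchly_gg(matrix(c(1, 1, 1, 1), 2), n = 10), "singular")
  # full agreement with stats::mauchly.test on a random 3-level factor:
  # the main-effect test operates on the factor's marginal means
  d <- random_rm_data(9, "a1", c("p", "q", "r"), seed = 31)
  d2 <- dplyr::bind_rows(dplyr::mutate(d, A = "a1"),
                         dplyr::mutate(d, A = "a2", y = y + rnorm(nrow(d))))
  marg <- dplyr::summarise(dplyr::group_by(d2, subject, B), y = mean(y),
                           .groups = "drop")
  wide <- tidyr::pivot_wider(marg, names_from = "B", values_from = "y")
  m <- as.matrix(wide[, -1])
  oracle <- stats::mauchly.test(stats::lm(m ~ 1), X = ~1)
  fit <- rm_anova(d2, dv = "y", subject = "subject", within = c("A", "B"))
  eff <- generics::tidy(fit)
  expect_equal(eff$mauchly_w[eff$effect == "B"],
               unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(eff$p_mauchly[eff$effect == "B"], oracle$p.value,
               tolerance = 1e-10)
})

test_that("epsilon stays within its theoretical bounds", {
  set.seed(77)
  for (i in 1:20) {
    p <- sample(3:5, 1)
    x <- matrix(rnorm(12 * p), 12, p)
    s <- stats::cov(x %*% awtsim:::orthonormal_contrasts(p))
    eps <- mauchly_gg(s, n = 12)$epsilon
    expect_gte(eps, 1 / (p - 1))
    expect_lte(eps, 1)
  }
})

test_that("GG-corrected p is adopted only when sphericity fails", {
  d <- random_rm_data(12, c("x", "y"), c("p", "q", "r"), seed = 55)
  fit <- rm_anova(d, dv = "y", subject = "subject", within = c("A", "B"))
  eff <- generics::tidy(fit)
  expect_equal(eff$p_reported,
               ifelse(eff$sphericity_violated, eff$p_gg, eff$p_value))
  expect_equal(eff$df_num_gg, eff$df_num * eff$epsilon)
})

test_that("pairwise comparisons apply the Bonferroni-adjusted alpha", {
  d <- random_rm_data(10, c("x", "y"), c("p", "q", "r"), seed = 9)
  pw <- pairwise_bonferroni(d, dv = "y", factor = "B")
  expect_equal(nrow(pw), 3)
  expect_equal(unique(pw$alpha_adjusted), 0.05 / 3, tolerance = 1e-12)
  expect_equal(round(unique(pw$alpha_adjusted), 3), 0.017)
  # marginal means collapse over the other factor
  sub_means <- tapply(d$y, list(d$subject, d$B), mean)
  expect_equal(pw$mean_diff[pw$level_1 == "p" & pw$level_2 == "q"],
               mean(sub_means[, "p"] - sub_means[, "q"]))
  # identical levels: zero differences, nothing significant
  d_id <- d
  d_id$y <- ave(d_id$y, d_id$subject, d_id$A)
  pw_id <- pairwise_bonferroni(d_id, dv = "y", factor = "B")
  expect_true(all(pw_id$mean_diff == 0))
  expect_false(any(pw_id$significant))
  # two levels need no correction
  pw2 <- pairwise_bonferroni(d, dv = "y", factor = "A")
  expect_equal(nrow(pw2), 1)
  expect_equal(pw2$alpha_adjusted, 0.05)
})

test_that("percent reduction reproduces its arithmetic", {
  expect_equal(percent_reduction(40, 20)$percent, 50)
  expect_equal(percent_reduction(33.3, 33.3)$percent, 0)
  expect_error(percent_reduction(0, 10), "positive")
  expect_error(percent_reduction(-3, 10), "positive")
})
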