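test_that("partial_corr matches the two-stage regression oracle", {
  set.seed(14)
  n <- 20
  z <- cbind(rnorm(n), rnorm(n))
  x <- 0.5 * z[, 1] + rnorm(n)
  y <- -0.3 * z[, 1] + 0.4 * x + rnorm(n)

  pc <- partial_corr(x, y, z)
  rx <- residuals(lm(x ~ z))
  ry <- residuals(lm(y ~ z))
  expect_equal(pc$r, cor(rx, ry), tolerance = 1e-10)
  ct <- cor.test(rx, ry)
  # same t statistic; df differ by the covariate count by construction
  expect_equal(pc$p_value,
               2 * pt(-abs(pc$r * sqrt((n - 4) / (1 - pc$r^2))), n - 4),
               tolerance = 1e-12)

  # no covariates: plain Pearson to machine accuracy
  pc0 <- partial_corr(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)

  # perfect confounding: y a copy of the covariate
  expect_lt(abs(partial_corr(x, z[, 1], z[, 1])$r), 1e-8)

  # rank-deficient covariates rejected
  expect_error(partial_corr(x, y, cbind(z[, 1], 2 * z[, 1])),
               "rank-deficient")

  # spearman variant equals rank-based oracle
  ps <- partial_corr(x, y, method = "spearman")
  expect_equal(ps$r, cor(x, y, method = "spearman"), tolerance = 1e-12)
})

test_that("glm recovers planted coefficients", {
  set.seed(8)
  n <- 26
  pma1 <- runif(n, 30, 37)
  days <- runif(n, 20, 90)
  # negligible noise: near-exact recovery
  y <- 0.2 + 0.01 * pma1 + rnorm(n, sd = 1e-9)
  fit <- glm_self_similarity(y, pma1, days)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "pma1"], 0.01, tolerance = 1e-6)
  expect_lt(td$p_value[td$term == "pma1"], 1e-10)
  expect_equal(glance(fit)$n_obs, n)

  # permuting the response destroys the association
  set.seed(9)
  y2 <- 0.2 + 0.01 * pma1 + rnorm(n, sd = 0.02)
  p_true <- tidy(glm_self_similarity(y2, pma1, days))$p_value[2]
  p_perm <- replicate(50, {
    tidy(glm_self_similarity(sample(y2), pma1, days))$p_value[2]
  })
  expect_lt(p_true, 0.05)
  expect_gt(median(p_perm), 0.05)

  expect_error(glm_self_similarity(y[1:4], pma1[1:4], days[1:4]),
               "at least 5")
})

test_that("lme reduces to OLS without grouping variance and honours structure", {
  set.seed(10)
  n <- 10
  panel <- toy_panel(n)
  cm <- toy_cohort_matrices(n, 15, noise = 0.3)
  s <- similarity_matrix(cm$tp1, cm$tp2, density = 0.5)

  # zero random-effect variance: fixed effects match OLS closely
  fit <- suppressWarnings(lme_self_to_other(s, panel, form = "days_only"))
  long_days <- outer(panel$pma_scan1, panel$pma_scan2,
                     function(a, b) (b - a) * 7)
  off <- row(s$values) != col(s$values)
  ols <- lm(s$values[off] ~ long_days[off])
  vc <- glance(fit)
  if (vc$sd_intercept < 1e-4) {
    expect_equal(tidy(fit)$estimate[2], coef(ols)[[2]], tolerance = 1e-4)
  }
  expect_equal(fit$n_obs, n * (n - 1))

  # planted random intercepts are detected; shuffling subject labels
  # shrinks the estimated intercept variance
  set.seed(11)
  subj_eff <- rnorm(n, sd = 0.2)
  v <- matrix(rnorm(n * n, sd = 0.02), n, n) + subj_eff +
    outer(rep(0, n), rep(0, n)) - 0.001 * long_days
  dimnames(v) <- list(panel$subject_id, panel$subject_id)
  s2 <- list_to_sim(v); s2$subjects <- panel$subject_id
  fit2 <- lme_self_to_other(s2, panel, form = "days_only",
                            include_self = TRUE)
  sd_true <- glance(fit2)$sd_intercept
  expect_gt(sd_true, 0.1)
  v_shuf <- v[sample(n), ]
  dimnames(v_shuf) <- dimnames(v)
  s3 <- list_to_sim(v_shuf); s3$subjects <- panel$subject_id
  fit3 <- suppressWarnings(lme_self_to_other(s3, panel, form = "days_only",
                                             include_self = TRUE))
  expect_lt(glance(fit3)$sd_intercept, sd_true)

  # cross-subject interval definition: (column pma2 - row pma1) * 7
  est_days <- tidy(fit2)$estimate[tidy(fit2)$term == "days"]
  expect_lt(abs(est_days - (-0.001)), 5e-4)
})

test_that("bonferroni adjusts, caps and flags", {
  out <- bonferroni(c(0.003, 0.02, 1.0), m = 7)
  expect_equal(out$p_adjusted, c(0.021, 0.14, 1))
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  expect_error(bonferroni(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni(rep(0.1, 9), m = 7), "family size")
  # idempotent in the flag sense: re-adjusting adjusted values with m = 1
  again <- bonferroni(out$p_adjusted, m = 3)$significant
  expect_true(all(which(again) %in% which(out$significant)))
})

test_that("motion analysis correlates FD with self-similarity and filters", {
  set.seed(15)
  n <- 31L
  panel <- toy_panel(n)
  panel$mean_fd_tp1 <- runif(n, 0.05, 0.6)
  panel$mean_fd_tp2 <- runif(n, 0.05, 0.6)
  # planted confound: self-similarity degrades with motion
  mean_fd <- (panel$mean_fd_tp1 + panel$mean_fd_tp2) / 2
  self_sim <- 0.6 - 0.5 * mean_fd + rnorm(n, sd = 0.05)

  res <- motion_analysis(self_sim, panel)
  expect_lt(res$correlation$r, 0)
  expect_lt(res$correlation$p_value, 0.05)
  keep <- panel$mean_fd_tp1 < 0.3 & panel$mean_fd_tp2 < 0.3
  expect_identical(res$subgroup$subject_id, panel$subject_id[keep])
  expect_identical(res$subgroup_self_sim, self_sim[keep])

  # all below threshold: filter is a no-op
  panel2 <- panel
  panel2$mean_fd_tp1 <- panel2$mean_fd_tp1 / 10
  panel2$mean_fd_tp2 <- panel2$mean_fd_tp2 / 10
  expect_identical(nrow(motion_analysis(self_sim, panel2)$subgroup), n)

  # degenerate threshold empties the subgroup with a warning, no error
  expect_warning(res0 <- motion_analysis(self_sim, panel, fd_threshold = 0),
                 "no subjects")
  expect_identical(nrow(res0$subgroup), 0L)

  panel$mean_fd_tp1[1] <- NA
  expect_error(motion_analysis(self_sim, panel), "missing mean framewise")
})
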