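test_that("identical score vectors give p = 1 and zero AUC difference", {
  set.seed(3)
  s <- runif(40); y <- rbinom(40, 1, 0.5)
  r <- delong_test(s, s, y)
  expect_equal(r$p, 1)
  expect_equal(r$auc_diff, 0)
  expect_equal(r$auc1, r$auc2)
})

test_that("perfectly separating scores have AUC 1", {
  y <- rep(0:1, each = 10)
  s1 <- y + seq(0, 0.5, length.out = 20)
  s2 <- runif(20)
  r <- delong_test(s1, s2, y)
  expect_equal(r$auc1, 1)
})

test_that("AUCs agree with the Mann-Whitney statistic including ties", {
  set.seed(7)
  y <- rbinom(60, 1, 0.4)
  s1 <- round(rnorm(60, y), 1)   # rounding makes ties
  s2 <- rnorm(60, 0.5 * y)
  r <- delong_test(s1, s2, y)
  expect_equal(r$auc1, bf_auc(s1, y))
  expect_equal(r$auc2, bf_auc(s2, y))
})

test_that("the DeLong variance is close to a bootstrap estimate", {
  set.seed(11)
  n <- 30
  latent <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.5 * latent))
  s1 <- latent + rnorm(n, sd = 0.7)
  s2 <- 0.5 * latent + rnorm(n, sd = 0.9)
  r <- delong_test(s1, s2, y)
  boots <- vapply(seq_len(1e4), function(i) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(y[idx])) == 2) break
    }
    bf_auc(s1[idx], y[idx]) - bf_auc(s2[idx], y[idx])
  }, 0)
  expect_lt(abs(r$se_diff^2 - var(boots)) / var(boots), 0.15)
})

test_that("unchanged risk predictions give NRI 0 and IDI 0", {
  set.seed(5)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  r <- nri_idi(p, p, y)
  expect_equal(r$nri, 0)
  expect_equal(r$idi, 0)
  expect_equal(r$nri_p, 1)
})

test_that("NRI and IDI equal the hand-worked six-subject computation", {
  y <- c(1, 1, 1, 0, 0, 0)
  p_old <- c(0.2, 0.4, 0.6, 0.3, 0.5, 0.7)
  p_new <- c(0.3, 0.3, 0.8, 0.2, 0.6, 0.6)
  # events: up, down, up -> P(up|ev) = 2/3, P(down|ev) = 1/3
  # nonevents: down, up, down -> P(down|ne) = 2/3, P(up|ne) = 1/3
  # NRI = (2/3 - 1/3) + (2/3 - 1/3) = 2/3
  # IDI = mean(+0.1, -0.1, +0.2) - mean(-0.1, +0.1, -0.1) = 1/15 + 1/30 = 0.1
  r <- nri_idi(p_old, p_new, y)
  expect_equal(r$nri, 2 / 3)
  expect_equal(r$idi, 0.1)
  # asymptotic SEs from the multinomial / delta-method formulas, by hand:
  se_nri <- sqrt((2/3 + 1/3 - (1/3)^2) / 3 + (2/3 + 1/3 - (1/3)^2) / 3)
  d_ev <- c(0.1, -0.1, 0.2); d_ne <- c(-0.1, 0.1, -0.1)
  se_idi <- sqrt(var(d_ev) / 3 + var(d_ne) / 3)
  expect_equal(r$nri_se, se_nri)
  expect_equal(r$idi_se, se_idi)
  expect_equal(r$nri_ci, r$nri + c(-1, 1) * 1.95996 * se_nri)
})

test_that("adding pure noise leaves NRI and IDI centred on zero", {
  stats <- t(vapply(1:30, function(i) {
    set.seed(400 + i)
    y <- rbinom(2000, 1, 0.4)
    p_old <- plogis(rnorm(2000, y))
    p_new <- plogis(qlogis(p_old) + rnorm(2000, sd = 0.1))
    r <- nri_idi(p_old, p_new, y)
    c(r$nri, r$idi)
  }, c(0, 0)))
  for (j in 1:2) {
    mc_se <- sd(stats[, j]) / sqrt(nrow(stats))
    expect_lt(abs(mean(stats[, j])), 3 * mc_se + 0.005)
  }
})

test_that("one-class outcomes are rejected", {
  expect_error(nri_idi(runif(5), runif(5), rep(1, 5)), "both outcome classes")
  expect_error(delong_test(runif(5), runif(5), rep(0, 5)), "both outcome classes")
})

test_that("identical raters give ICC 1 and independent raters near 0", {
  m <- cbind(seq(1, 20, length.out = 12), seq(1, 20, length.out = 12))
  expect_equal(icc_agreement(m)$mean_icc, 1)
  set.seed(9)
  noisy <- cbind(rnorm(200), rnorm(200))
  expect_lt(abs(icc_agreement(noisy)$mean_icc), 0.15)
})

test_that("ICC(2,1) matches the direct ANOVA-table computation", {
  set.seed(17)
  subj <- rnorm(10, sd = 3)
  rater_bias <- c(0, 0.8)
  m <- outer(subj, rep(1, 2)) + outer(rep(1, 10), rater_bias) +
    matrix(rnorm(20, sd = 0.6), 10, 2)
  got <- icc_agreement(m)$icc[[1]]
  # independent route: mean squares from stats::aov on the long layout
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(1:10, 2)),
                     rater = factor(rep(1:2, each = 10)))
  ms <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]$`Mean Sq`
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  want <- (msr - mse) / (msr + (2 - 1) * mse + (2 / 10) * (msc - mse))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("per-measurement ICCs average into the summary", {
  set.seed(23)
  mats <- lapply(1:5, function(i) {
    s <- rnorm(15, sd = 3)
    cbind(s + rnorm(15, sd = 0.3), s + rnorm(15, sd = 0.3))
  })
  names(mats) <- c("breast", "fat", "fgt", "tumor", "interface")
  r <- icc_agreement(mats)
  expect_length(r$icc, 5)
  expect_equal(r$mean_icc, mean(r$icc))
  expect_true(all(r$icc > 0.9))
})

test_that("nested model comparison respects the AIC identity", {
  coh <- simulate_cohort(cohort_config(n_patients = 1004, seed = 77))
  coh <- dichotomize_interface(coh, 2.36)
  mc <- compare_models(coh, c("her2", "ct_stage"))
  dparams <- length(mc$fit_combined$coefficients) -
    length(mc$fit_conventional$coefficients)
  expect_equal(mc$aic_combined - mc$aic_conventional,
               2 * dparams - 2 * (mc$fit_combined$log_lik -
                                    mc$fit_conventional$log_lik),
               tolerance = 1e-10)
  expect_identical(mc$fit_combined$predictors,
                   c(mc$fit_conventional$predictors, "interface_group"))
  expect_true(mc$auc_combined >= 0 && mc$auc_combined <= 1)
})
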