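test_that("a flat 2x2 table has OR 1 with a log-symmetric CI", {
  r <- odds_ratio_2x2(10, 10, 10, 10)
  expect_equal(r$or, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high))
})

test_that("zero cells are rejected", {
  expect_error(odds_ratio_2x2(0, 10, 5, 5), "zero cell")
})

test_that("reported univariable odds ratios reproduce from the 2x2 counts", {
  counts <- reported_counts()
  expected <- list(
    c("interface_group", "development", 1.626),
    c("interface_group", "validation", 2.894),
    c("her2", "development", 4.104),
    c("er", "development", 0.459),
    c("pr", "validation", 0.238))
  for (e in expected) {
    row <- counts[counts$variable == e[1] & counts$cohort == e[2], ]
    r <- odds_ratio_2x2(row$a, row$b, row$c, row$d)
    expect_equal(round(r$or, 3), as.numeric(e[3]))
  }
})

test_that("Youden cutoff solves perfect separation", {
  r <- youden_cutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$cutoff, 3)
  expect_equal(r$j, 1)
  expect_equal(r$j, r$sensitivity + r$specificity - 1)
})

test_that("Youden cutoff equals the exhaustive threshold scan", {
  for (seed in 1:15) {
    dat <- withr::with_seed(seed, {
      y <- rbinom(50, 1, 0.5)
      list(v = rnorm(50, mean = 0.8 * y), y = y)
    })
    got <- youden_cutoff(dat$v, dat$y)
    want <- bf_youden(dat$v, dat$y)
    expect_equal(got$j, want$j)
    expect_equal(got$cutoff, want$cutoff)
  }
})

test_that("Youden J of signal data clears the permutation distribution", {
  set.seed(21)
  y <- rbinom(60, 1, 0.5)
  v <- rnorm(60, mean = 2 * y)
  j_obs <- youden_cutoff(v, y)$j
  j_perm <- vapply(1:1000, function(i) youden_cutoff(v, sample(y))$j, 0)
  expect_gt(j_obs, quantile(j_perm, 0.99))
  expect_lt(median(j_perm), 0.5)
})

test_that("one-class outcomes and constant markers are rejected", {
  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
  expect_error(youden_cutoff(rep(2, 4), c(0, 1, 0, 1)), "distinct")
})

test_that("a single binary predictor reproduces the closed-form 2x2 OR", {
  coh <- simulate_cohort(cohort_config(n_patients = 800, seed = 31))
  coh <- dichotomize_interface(coh, 2.36)
  fit <- fit_logistic(coh, "interface_group")
  tab <- table(coh$interface_group, factor(coh$pcr, levels = c(1, 0)))
  r <- odds_ratio_2x2(unclass(tab))
  i <- which(fit$or_table$term == "interface_groupHigh")
  expect_equal(fit$or_table$or[i], r$or, tolerance = 1e-6)
  expect_equal(fit$or_table$ci_low[i], r$ci_low, tolerance = 1e-6)
  expect_equal(fit$or_table$ci_high[i], r$ci_high, tolerance = 1e-6)
})

test_that("the intercept-only model fits the event proportion", {
  coh <- simulate_cohort(cohort_config(n_patients = 400, seed = 8))
  coh$dummy <- factor(rep(c("a", "b"), 200))
  fit <- fit_logistic(coh, "dummy")
  expect_equal(mean(fitted(fit$glm)), mean(1 - coh$pcr), tolerance = 1e-8)
  expect_equal(fit$aic, 2 * length(fit$coefficients) - 2 * fit$log_lik)
})

test_that("constant predictors and separation are clear errors", {
  coh <- simulate_cohort(cohort_config(n_patients = 100, seed = 2))
  coh$flat <- factor(rep("x", 100), levels = c("x", "y"))
  expect_error(fit_logistic(coh, "flat"), "constant")
  coh$sep <- factor(ifelse(coh$pcr == 1, "a", "b"))
  expect_error(suppressWarnings(fit_logistic(coh, "sep")), "separation|converge")
})

test_that("the p < 0.05 entry rule selects predictors, excluding the composite", {
  fake <- function(p) structure(list(overall_p = p), class = "logistic_fit")
  fits <- list(a = fake(0.01), b = fake(0.20), c = fake(0.049))
  expect_identical(select_multivariable(fits), c("a", "c"))
  expect_warning(sel0 <- select_multivariable(list(a = fake(0.2), b = fake(0.8))),
                 "empty")
  expect_length(sel0, 0)
  fits2 <- list(her2 = fake(0.001), subtype = fake(0.001), age = fake(0.6))
  expect_identical(select_multivariable(fits2), "her2")
})

test_that("strong predictors are selected almost always, null ones rarely", {
  hits <- vapply(1:40, function(i) {
    coh <- simulate_cohort(cohort_config(
      n_patients = 1004, seed = 7000 + i,
      true_log_odds = c(intercept = 0.3, her2_negative = log(4))))
    coh <- dichotomize_interface(coh, 2.36)
    fits <- lapply(c("her2", "bmi"), function(p) fit_logistic(coh, p))
    names(fits) <- c("her2", "bmi")
    sel <- suppressWarnings(select_multivariable(fits))
    c("her2" %in% sel, "bmi" %in% sel)
  }, c(TRUE, TRUE))
  expect_gte(mean(hits[1, ]), 0.95)
  expect_lte(mean(hits[2, ]), 0.25)
})

test_that("VIF is 1 for orthogonal predictors and closed-form for a known r", {
  n <- 64
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  dat <- data.frame(x1 = x1, x2 = x2)
  v <- vif(dat, c("x1", "x2"))
  expect_equal(as.numeric(v), c(1, 1))

  set.seed(4)
  a <- rnorm(500); b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(500)
  r2 <- cor(a, b)^2
  v2 <- vif(data.frame(a = a, b = b), c("a", "b"))
  expect_equal(as.numeric(v2), rep(1 / (1 - r2), 2), tolerance = 1e-10)
})

test_that("VIF agrees with the car implementation on a numeric design", {
  set.seed(6)
  dat <- data.frame(a = rnorm(200))
  dat$b <- 0.6 * dat$a + rnorm(200)
  dat$c <- rnorm(200)
  dat$y <- rnorm(200)
  ours <- vif(dat, c("a", "b", "c"))
  theirs <- car::vif(lm(y ~ a + b + c, data = dat))
  expect_equal(as.numeric(ours), as.numeric(theirs), tolerance = 1e-10)
})

test_that("a duplicated predictor is flagged as infinite VIF", {
  dat <- data.frame(a = rnorm(50))
  dat$b <- dat$a
  expect_warning(v <- vif(dat, c("a", "b")), "exceeds")
  expect_true(all(is.infinite(v)))
})

test_that("group comparisons use the right tests and flag the interface effect", {
  # cohort rebuilt from the reported development interface-group counts
  coh <- data.frame(
    pcr = rep(c(1L, 0L, 1L, 0L), c(250, 358, 119, 277)),
    interface_group = factor(rep(c("Low", "Low", "High", "High"),
                                 c(250, 358, 119, 277)),
                             levels = c("Low", "High")))
  out <- compare_groups(coh, by = "pcr", vars = "interface_group")
  expect_identical(unique(out$test), "chisq")
  expect_lt(out$p[1], 0.001)

  coh2 <- simulate_cohort(cohort_config(n_patients = 400, seed = 11,
                                        true_log_odds = c(intercept = 0)))
  out2 <- compare_groups(coh2, by = "pcr",
                         vars = c("age", "interface_volume_cm3", "her2"))
  expect_identical(out2$test[out2$variable == "age"], "wilcoxon")
  expect_true(all(out2$p > 0 & out2$p <= 1))
})

test_that("identical groups give p in the null region", {
  x <- c(rnorm(30), rnorm(30))
  g <- rep(0:1, each = 30)
  coh <- data.frame(pcr = g, v = sample(x))
  set.seed(2)
  ps <- vapply(1:50, function(i) {
    coh$v <- sample(x)
    compare_groups(coh, by = "pcr", vars = "v")$p[1]
  }, 0)
  expect_gt(mean(ps > 0.05), 0.8)
})

test_that("Spearman matrix is exact on ranks and monotone-invariant", {
  set.seed(13)
  x <- data.frame(a = rnorm(20), b = rnorm(20), c = runif(20))
  m <- spearman_matrix(x)
  expect_equal(unname(diag(m)), rep(1, 3))
  # brute force: Pearson correlation of midranks
  brute <- cor(apply(as.matrix(x), 2, rank))
  expect_equal(m, brute, tolerance = 1e-12)
  x2 <- transform(x, a = exp(a), b = b^3)
  expect_equal(spearman_matrix(x2), m, tolerance = 1e-12)
})
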