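#' Odds ratio from a 2x2 table with Wald confidence interval
#'
#' Orientation: rows are the exposure levels \code{(reference, index)} (for
#' the interface biomarker: low, high), columns are the outcome
#' \code{(pCR, non-pCR)}. The reported odds ratio is the odds of non-pCR in
#' the index level relative to the reference level, matching the published
#' univariable tables where non-pCR is the modelled event. The 95% CI is
#' Wald on the log scale with SE = sqrt(1/a + 1/b + 1/c + 1/d).
#'
#' @param a,b reference-level pCR and non-pCR counts.
#' @param c,d index-level pCR and non-pCR counts. Alternatively pass a 2x2
#'   matrix as \code{a}.
#' @param conf_z normal quantile for the CI (default 1.95996).
#' @return List of class \code{odds_ratio}: \code{or}, \code{ci_low},
#'   \code{ci_high}, \code{log_or}, \code{se_log_or}, \code{p} (Wald).
#' @export
odds_ratio_2x2 <- function(a, b = NULL, c = NULL, d = NULL, conf_z = 1.95996) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4L, all(cells >= 0), all(cells == round(cells)),
            sum(cells) >= 1)
  if (any(cells == 0))
    stop("2x2 table has a zero cell; continuity-corrected odds ratios are ",
         "out of scope")
  log_or <- log((d / b) / (c / a))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  structure(list(or = exp(log_or),
                 ci_low = exp(log_or - conf_z * se),
                 ci_high = exp(log_or + conf_z * se),
                 log_or = log_or, se_log_or = se,
                 p = 2 * stats::pnorm(-abs(log_or / se))),
            class = "odds_ratio")
}

#' Optimal dichotomization cutoff by Youden's J
#'
#' Scans every distinct observed marker value as a candidate cutoff under
#' the rule "predict the positive class when value >= cutoff", and returns
#' the cutoff maximizing J = sensitivity + specificity - 1. Ties are broken
#' by the smallest such cutoff.
#'
#' @param values numeric marker (here: interface volume in cm^3).
#' @param outcomes binary vector, 1 = positive class (non-pCR in the
#'   originating study).
#' @return List of class \code{cutoff_result}: \code{cutoff}, \code{j},
#'   \code{sensitivity}, \code{specificity}.
#' @export
youden_cutoff <- function(values, outcomes) {
  stopifnot(length(values) == length(outcomes), all(outcomes %in% 0:1))
  if (length(unique(outcomes)) < 2L)
    stop("both outcome classes must be present to locate a cutoff")
  cand <- sort(unique(values))
  if (length(cand) < 2L) stop("need at least 2 distinct marker values")
  pos <- values[outcomes == 1]
  neg <- values[outcomes == 0]
  sens <- vapply(cand, function(ct) mean(pos >= ct), 0)
  spec <- vapply(cand, function(ct) mean(neg < ct), 0)
  j <- sens + spec - 1
  i <- which(j == max(j))[1]     # candidates ascending -> smallest tied cutoff
  structure(list(cutoff = cand[i], j = j[i],
                 sensitivity = sens[i], specificity = spec[i]),
            class = "cutoff_result")
}

#' Maximum-likelihood logistic regression fit
#'
#' Fits a binomial GLM by iteratively reweighted least squares (convergence
#' tolerance 1e-8, at most 100 iterations) for the event non-pCR
#' (\code{1 - pcr}) by default, and tabulates odds ratios with Wald 95%
#' confidence intervals and z-test p-values per coefficient, plus a
#' likelihood-ratio p-value for the predictor set as a whole. Categorical
#' predictors are expanded against their first factor level (the reference
#' level of the published tables).
#'
#' @param cohort cohort table containing the predictors and \code{pcr}.
#' @param predictors character vector of column names.
#' @param event \code{"non-pCR"} (default) models 1 - pcr; \code{"pCR"}
#'   models pcr.
#' @param conf_z normal quantile for the CIs.
#' @return Object of class \code{logistic_fit}: \code{coefficients},
#'   \code{vcov}, \code{or_table} (term, estimate, se, or, ci_low, ci_high,
#'   p), \code{log_lik}, \code{aic}, \code{n}, \code{overall_p} (LRT against
#'   the intercept-only model), \code{glm} (the underlying fit),
#'   \code{predictors}.
#' @export
fit_logistic <- function(cohort, predictors, event = c("non-pCR", "pCR"),
                         conf_z = 1.95996) {
  event <- match.arg(event)
  stopifnot(all(predictors %in% names(cohort)), "pcr" %in% names(cohort),
            all(cohort$pcr %in% 0:1))
  y <- if (event == "non-pCR") 1L - cohort$pcr else cohort$pcr
  dat <- droplevels(cohort[, predictors, drop = FALSE])
  for (p in predictors) {
    v <- dat[[p]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("predictor '", p, "' is constant")
  }
  dat$.y <- y
  if (length(dat$.y) <= length(predictors) + 1L)
    stop("more parameters than observations")
  fml <- stats::as.formula(paste(".y ~", paste(predictors, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = dat,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("logistic fit did not converge for predictors: ",
                           paste(predictors, collapse = ", "))
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  big <- names(co)[abs(co) > 15 & names(co) != "(Intercept)"]
  if (length(big))
    stop("separation suspected (diverging coefficient) for: ",
         paste(big, collapse = ", "))
  or_table <- data.frame(term = names(co), estimate = unname(co),
                         se = unname(se), or = exp(unname(co)),
                         ci_low = exp(unname(co - conf_z * se)),
                         ci_high = exp(unname(co + conf_z * se)),
                         p = 2 * stats::pnorm(-abs(unname(co / se))),
                         row.names = NULL)
  null_fit <- stats::glm(.y ~ 1, family = stats::binomial(), data = dat)
  lrt <- stats::anova(null_fit, fit, test = "Chisq")
  structure(list(coefficients = co, vcov = stats::vcov(fit),
                 or_table = or_table,
                 log_lik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit), n = nrow(dat),
                 overall_p = lrt$`Pr(>Chi)`[2],
                 glm = fit, predictors = predictors, event = event),
            class = "logistic_fit")
}

#' Predictor selection for the multivariable model
#'
#' Applies the entry rule used in the originating analysis: predictors whose
#' univariable likelihood-ratio p-value is below \code{alpha} enter the
#' multivariable model. When the receptor components (er/pr/her2) are
#' themselves selected, the composite molecular subtype is excluded even if
#' significant, since it is a deterministic function of them.
#'
#' @param fits named list of univariable \code{logistic_fit}s (names =
#'   predictor names).
#' @param alpha entry threshold (default 0.05).
#' @param composite name of the composite predictor (default "subtype");
#'   \code{components} its components.
#' @return Character vector of selected predictor names (possibly empty,
#'   with a warning).
#' @export
select_multivariable <- function(fits, alpha = 0.05, composite = "subtype",
                                 components = c("er", "pr", "her2")) {
  stopifnot(is.list(fits), !is.null(names(fits)))
  p <- vapply(fits, function(f) f$overall_p, 0)
  sel <- names(fits)[p < alpha]
  if (composite %in% sel && any(components %in% sel))
    sel <- setdiff(sel, composite)
  if (!length(sel)) warning("no predictor met the univariable p < ", alpha,
                            " entry rule; selection is empty")
  sel
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression of
#' predictor column j on all other predictor columns (categorical predictors
#' expanded to indicator columns first). Values above \code{flag_above}
#' indicate worrying multicollinearity; an exactly collinear column yields
#' \code{Inf}.
#'
#' @param cohort data frame.
#' @param predictors character vector of column names.
#' @param flag_above flag threshold (default 5).
#' @return Named numeric vector of VIFs, with attribute \code{flagged}.
#' @export
vif <- function(cohort, predictors, flag_above = 5) {
  stopifnot(all(predictors %in% names(cohort)))
  fml <- stats::as.formula(paste("~", paste(predictors, collapse = " + ")))
  X <- stats::model.matrix(fml, data = cohort)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2L) {
    out <- stats::setNames(rep(1, ncol(X)), colnames(X))
    attr(out, "flagged") <- character(0)
    return(out)
  }
  out <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(out) <- colnames(X)
  flagged <- names(out)[out > flag_above]
  if (length(flagged))
    warning("VIF exceeds ", flag_above, " for: ", paste(flagged, collapse = ", "))
  attr(out, "flagged") <- flagged
  out
}

#' Group comparison table (development-cohort style)
#'
#' Compares each variable between outcome groups the way the cohort tables
#' of the originating study are built: continuous variables with a two-sided
#' Wilcoxon rank-sum test (normal approximation with tie correction),
#' summarized as median [IQR]; categorical variables with the chi-squared
#' test, falling back to Fisher's exact test when any expected cell count is
#' below 5, summarized as counts (percent).
#'
#' @param cohort cohort table.
#' @param by name of the binary grouping column (default "pcr").
#' @param vars variables to compare; defaults to the standard clinical set
#'   present in the table.
#' @return \code{data.frame}: variable, level, summaries per group, test
#'   used, p-value (repeated across a variable's levels).
#' @export
compare_groups <- function(cohort, by = "pcr", vars = NULL) {
  stopifnot(by %in% names(cohort))
  g <- factor(cohort[[by]])
  stopifnot(nlevels(g) == 2L)
  if (is.null(vars))
    vars <- intersect(c("age", "bmi", "interface_volume_cm3", "ct_stage",
                        "cn_stage", "er", "pr", "her2", "ki67", "menopause",
                        "subtype", "interface_group"), names(cohort))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    if (is.numeric(x)) {
      p <- stats::wilcox.test(x ~ g, exact = FALSE, correct = TRUE)$p.value
      sm <- vapply(levels(g), function(l) {
        q <- stats::quantile(x[g == l], c(0.5, 0.25, 0.75), na.rm = TRUE)
        sprintf("%.2f [%.2f, %.2f]", q[1], q[2], q[3])
      }, "")
      data.frame(variable = v, level = "", group1 = sm[1], group2 = sm[2],
                 test = "wilcoxon", p = p)
    } else {
      x <- droplevels(factor(x))
      tab <- table(x, g)
      expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected
      if (any(expected < 5)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher"
      } else {
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
        test <- "chisq"
      }
      pct <- prop.table(tab, margin = 2) * 100
      data.frame(variable = v, level = rownames(tab),
                 group1 = sprintf("%d (%.1f)", tab[, 1], pct[, 1]),
                 group2 = sprintf("%d (%.1f)", tab[, 2], pct[, 2]),
                 test = test, p = p)
    }
  })
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(by, "_", levels(g))
  out
}

#' Spearman rank-correlation matrix
#'
#' Pairwise Spearman rho (tie-corrected via midranks) across the volumetric
#' columns of a measurement table.
#' @param x data frame or matrix of numeric columns.
#' @return Symmetric correlation matrix.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  stopifnot(is.numeric(x))
  stats::cor(x, method = "spearman", use = "pairwise.complete.obs")
}
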