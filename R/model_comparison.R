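#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two risk scores measured on the same subjects. AUCs
#' are the Mann-Whitney statistics (midranks for ties); the variance of the
#' paired AUC difference uses DeLong's placement-value covariance estimator,
#' and the p-value is two-sided normal. Exactly identical score vectors have
#' a zero difference with zero estimated variance; that degenerate case is
#' reported as p = 1.
#'
#' @param scores1,scores2 numeric risk scores (higher = more likely
#'   positive), paired by subject.
#' @param outcomes binary, 1 = positive class.
#' @return List of class \code{delong_result}: \code{auc1}, \code{auc2},
#'   \code{auc_diff}, \code{se_diff}, \code{p}.
#' @export
delong_test <- function(scores1, scores2, outcomes) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(outcomes), all(outcomes %in% 0:1))
  if (length(unique(outcomes)) < 2L) stop("both outcome classes must be present")
  if (isTRUE(all.equal(scores1, scores2, tolerance = 0))) {
    a <- as.numeric(pROC::auc(pROC::roc(outcomes, scores1, levels = c(0, 1),
                                        direction = "<", quiet = TRUE)))
    return(structure(list(auc1 = a, auc2 = a, auc_diff = 0, se_diff = 0, p = 1),
                     class = "delong_result"))
  }
  r1 <- pROC::roc(outcomes, scores1, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  r2 <- pROC::roc(outcomes, scores2, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  tst <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  auc1 <- as.numeric(pROC::auc(r1)); auc2 <- as.numeric(pROC::auc(r2))
  z <- as.numeric(tst$statistic)
  se <- if (is.finite(z) && abs(z) > 0) abs(auc1 - auc2) / abs(z) else NA_real_
  structure(list(auc1 = auc1, auc2 = auc2, auc_diff = auc1 - auc2,
                 se_diff = se, p = as.numeric(tst$p.value)),
            class = "delong_result")
}

#' Continuous NRI and IDI for nested risk models
#'
#' Category-free net reclassification improvement and integrated
#' discrimination improvement of a new risk model over an old one on the
#' same subjects.
#' NRI = P(up|event) - P(down|event) + P(down|nonevent) - P(up|nonevent),
#' where up/down means any increase/decrease in predicted probability. IDI
#' is the difference in discrimination slopes:
#' (mean new - mean old probability among events) - (same among nonevents).
#' Standard errors are the asymptotic ones of the standard continuous-NRI
#' formulation (multinomial variance of the event and nonevent net
#' proportions; delta-method variance of the mean risk differences), with
#' two-sided normal p-values. A percentile bootstrap CI is available via
#' \code{n_boot}.
#'
#' @param probs_old,probs_new predicted probabilities in [0,1], paired.
#' @param outcomes binary, 1 = event.
#' @param conf_z normal quantile for CIs.
#' @param n_boot if > 0, number of bootstrap resamples for percentile CIs.
#' @param boot_seed seed for the bootstrap.
#' @return List of class \code{reclassification_result} with components
#'   \code{nri}, \code{nri_ci}, \code{nri_p}, \code{idi}, \code{idi_ci},
#'   \code{idi_p} (and \code{nri_boot_ci}, \code{idi_boot_ci} when
#'   bootstrapped).
#' @export
nri_idi <- function(probs_old, probs_new, outcomes, conf_z = 1.95996,
                    n_boot = 0L, boot_seed = 1L) {
  stopifnot(length(probs_old) == length(probs_new),
            length(probs_old) == length(outcomes),
            all(probs_old >= 0 & probs_old <= 1),
            all(probs_new >= 0 & probs_new <= 1), all(outcomes %in% 0:1))
  ev <- outcomes == 1
  if (!any(ev) || all(ev)) stop("both outcome classes must be present")

  point <- function(po, pn, ev) {
    up <- pn > po; down <- pn < po
    n_e <- sum(ev); n_ne <- sum(!ev)
    pu_e <- mean(up[ev]); pd_e <- mean(down[ev])
    pu_n <- mean(up[!ev]); pd_n <- mean(down[!ev])
    nri_e <- pu_e - pd_e; nri_n <- pd_n - pu_n
    d <- pn - po
    list(nri = nri_e + nri_n,
         nri_var = (pu_e + pd_e - (pu_e - pd_e)^2) / n_e +
           (pu_n + pd_n - (pd_n - pu_n)^2) / n_ne,
         idi = mean(d[ev]) - mean(d[!ev]),
         idi_var = stats::var(d[ev]) / n_e + stats::var(d[!ev]) / n_ne)
  }
  est <- point(probs_old, probs_new, ev)
  nri_se <- sqrt(est$nri_var); idi_se <- sqrt(est$idi_var)
  pz <- function(x, se) {
    if (se == 0) return(if (x == 0) 1 else 0)   # no reclassification at all
    2 * stats::pnorm(-abs(x / se))
  }
  out <- list(nri = est$nri,
              nri_ci = c(est$nri - conf_z * nri_se, est$nri + conf_z * nri_se),
              nri_se = nri_se, nri_p = pz(est$nri, nri_se),
              idi = est$idi,
              idi_ci = c(est$idi - conf_z * idi_se, est$idi + conf_z * idi_se),
              idi_se = idi_se, idi_p = pz(est$idi, idi_se))
  if (n_boot > 0) {
    bs <- withr::with_seed(boot_seed, {
      vapply(seq_len(n_boot), function(i) {
        repeat {
          idx <- sample.int(length(ev), replace = TRUE)
          if (any(ev[idx]) && !all(ev[idx])) break
        }
        e <- point(probs_old[idx], probs_new[idx], ev[idx])
        c(e$nri, e$idi)
      }, c(0, 0))
    })
    out$nri_boot_ci <- unname(stats::quantile(bs[1, ], c(0.025, 0.975)))
    out$idi_boot_ci <- unname(stats::quantile(bs[2, ], c(0.025, 0.975)))
  }
  structure(out, class = "reclassification_result")
}

#' Interobserver agreement by intraclass correlation
#'
#' ICC(2,1): two-way random-effects, absolute-agreement, single-measure
#' intraclass correlation, computed from the two-way ANOVA mean squares
#' (subjects x raters):
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#'
#' @param ratings either an n x k numeric matrix (subjects x raters) for one
#'   measurement, or a named list of such matrices (one per volumetric
#'   measurement).
#' @return List of class \code{icc_result}: \code{icc} (named vector, one
#'   per measurement) and \code{mean_icc}.
#' @export
icc_agreement <- function(ratings) {
  one <- function(m) {
    m <- as.matrix(m)
    stopifnot(is.numeric(m), nrow(m) >= 2L, ncol(m) >= 2L, !anyNA(m))
    n <- nrow(m); k <- ncol(m)
    grand <- mean(m)
    row_m <- rowMeans(m); col_m <- colMeans(m)
    ssr <- k * sum((row_m - grand)^2)
    ssc <- n * sum((col_m - grand)^2)
    sse <- sum((m - outer(row_m, rep(1, k)) -
                  outer(rep(1, n), col_m) + grand)^2)
    msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  if (is.list(ratings) && !is.data.frame(ratings)) {
    icc <- vapply(ratings, one, 0)
  } else {
    icc <- c(measurement = one(ratings))
  }
  structure(list(icc = icc, mean_icc = mean(icc)), class = "icc_result")
}

#' Compare a conventional and a combined (interface-augmented) risk model
#'
#' Fits the nested pair of logistic models for non-pCR — the conventional
#' model on the selected clinical predictors, and the combined model adding
#' the dichotomized interface group — then compares them by DeLong's test on
#' the fitted risks, continuous NRI and IDI, and AIC.
#'
#' @param cohort dichotomized cohort table.
#' @param conventional_predictors character vector for the conventional model.
#' @param interface_var name of the added predictor (default
#'   "interface_group").
#' @return List of class \code{model_comparison}: \code{auc_conventional},
#'   \code{auc_combined}, \code{delong_p}, \code{nri}, \code{nri_ci},
#'   \code{nri_p}, \code{idi}, \code{idi_ci}, \code{idi_p},
#'   \code{aic_conventional}, \code{aic_combined}, plus both
#'   \code{logistic_fit}s.
#' @export
compare_models <- function(cohort, conventional_predictors,
                           interface_var = "interface_group") {
  stopifnot(interface_var %in% names(cohort))
  fit_conv <- fit_logistic(cohort, conventional_predictors)
  fit_comb <- fit_logistic(cohort, c(conventional_predictors, interface_var))
  y <- 1L - cohort$pcr
  p_conv <- stats::fitted(fit_conv$glm)
  p_comb <- stats::fitted(fit_comb$glm)
  dl <- delong_test(p_conv, p_comb, y)
  ri <- nri_idi(p_conv, p_comb, y)
  structure(list(auc_conventional = dl$auc1, auc_combined = dl$auc2,
                 delong_p = dl$p,
                 nri = ri$nri, nri_ci = ri$nri_ci, nri_p = ri$nri_p,
                 idi = ri$idi, idi_ci = ri$idi_ci, idi_p = ri$idi_p,
                 aic_conventional = fit_conv$aic, aic_combined = fit_comb$aic,
                 fit_conventional = fit_conv, fit_combined = fit_comb),
            class = "model_comparison")
}
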