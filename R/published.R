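#' Reported contingency counts from the originating cohorts
#'
#' The study that introduced the tumor-fat interface biomarker reported its
#' development (n = 1004) and external validation (n = 136) cohorts only as
#' summary tables; the patient-level data are not public. The published
#' contingency counts are, however, sufficient to recompute every
#' unadjusted (univariable) odds ratio and group pCR rate exactly. This
#' function returns those counts in the package's 2x2 orientation: rows
#' (reference level, index level), columns (pCR, non-pCR).
#'
#' @return A \code{data.frame} with columns \code{variable}, \code{cohort}
#'   ("development"/"validation"), \code{reference}, \code{index} (level
#'   names), and counts \code{a} (ref, pCR), \code{b} (ref, non-pCR),
#'   \code{c} (index, pCR), \code{d} (index, non-pCR).
#' @examples
#' counts <- reported_counts()
#' dev <- counts[counts$variable == "interface_group" &
#'               counts$cohort == "development", ]
#' odds_ratio_2x2(dev$a, dev$b, dev$c, dev$d)   # OR 1.626, CI 1.242-2.127
#' @export
reported_counts <- function() {
  rows <- list(
    # interface group: reference Low, index High
    list("interface_group", "development", "Low", "High", 250, 358, 119, 277),
    list("interface_group", "validation",  "Low", "High",  34,  47,  11,  44),
    # HER2: reference Positive, index Negative
    list("her2", "development", "Positive", "Negative", 233, 187, 136, 448),
    list("her2", "validation",  "Positive", "Negative",  28,  31,  17,  60),
    # ER: reference Positive, index Negative
    list("er", "development", "Positive", "Negative", 122, 329, 247, 306),
    list("er", "validation",  "Positive", "Negative",  16,  64,  29,  27),
    # PR: reference Positive, index Negative
    list("pr", "development", "Positive", "Negative",  61, 258, 308, 377),
    list("pr", "validation",  "Positive", "Negative",  12,  55,  33,  36),
    # Ki-67: reference >=20%, index <20%
    list("ki67", "development", ">=20%", "<20%", 336, 539,  33,  96),
    list("ki67", "validation",  ">=20%", "<20%",  43,  72,   2,  19))
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(variable = r[[1]], cohort = r[[2]], reference = r[[3]],
               index = r[[4]], a = r[[5]], b = r[[6]], c = r[[7]], d = r[[8]])))
  out
}

#' Reported cohort-level pCR counts
#'
#' Overall and per-interface-group pCR counts of the originating cohorts,
#' from which the published pCR rates (development 36.8%, validation 33.1%;
#' development low/high interface groups 41.1%/30.1%, validation 42.0%/20.0%)
#' follow by division.
#' @return \code{data.frame} with columns \code{cohort}, \code{group},
#'   \code{pcr}, \code{n}.
#' @export
reported_pcr_counts <- function() {
  data.frame(
    cohort = c("development", "validation",
               "development", "development", "validation", "validation"),
    group = c("all", "all", "Low", "High", "Low", "High"),
    pcr = c(369, 45, 250, 119, 34, 11),
    n = c(1004, 136, 608, 396, 81, 55))
}

#' Published dichotomization cutoff for the interface volume
#'
#' The optimal Youden's J cutoff derived in the development cohort and then
#' applied unchanged to the validation cohort: 2.36 cm^3. Patients at or
#' above it form the high-interface group.
#' @return Numeric scalar, cm^3.
#' @export
reported_cutoff_cm3 <- function() 2.36
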