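#' Call embryo sex from PCR amplicon observations
#'
#' Embryos are sexed with a duplex PCR: an autosomal control amplicon and a
#' Y-chromosome-specific amplicon. An embryo is called male if both amplicons
#' are present, female if only the autosomal amplicon is detected, and
#' undetermined (sexing failure) if the autosomal control is absent, whatever
#' the Y lane shows -- without the control, absence of the Y band is
#' uninformative.
#'
#' @param autosomal logical (or "present"/"absent"): autosomal amplicon seen.
#' @param y logical (or "present"/"absent"): Y-linked amplicon seen.
#' @return character vector in \code{c("male", "female", "undetermined")}.
#' @examples
#' callSexFromAmplicons(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
callSexFromAmplicons <- function(autosomal, y) {
    autosomal <- .asPresence(autosomal)
    y <- .asPresence(y)
    if (length(autosomal) != length(y))
        stop("amplicon vectors must have equal length")
    out <- rep("undetermined", length(autosomal))
    out[autosomal & y] <- "male"
    out[autosomal & !y] <- "female"
    out
}

.asPresence <- function(x) {
    if (is.character(x)) x <- x == "present"
    as.logical(x)
}

#' Verify amplicon sex calls against Y-linked gene expression
#'
#' Male embryos express Y-linked genes; female embryos show low/no Y
#' expression. A sample is called male when its mean TPM over the supplied
#' Y-gene set exceeds \code{threshold}, and the calls are compared with the
#' amplicon-based calls sample by sample.
#'
#' @param tpm TPM matrix (genes x samples) or a \linkS4class{SexExperiment}
#'   with a \code{tpm} assay.
#' @param yGeneIds character: Y-linked gene ids (must appear in the matrix).
#' @param threshold numeric: mean-TPM cutoff for a male call (default 1).
#' @param ampliconSex optional character vector of amplicon calls to compare
#'   against (same order as samples).
#' @return A data.frame with per-sample \code{mean_y_tpm},
#'   \code{expression_sex}, and, when amplicon calls are given,
#'   \code{amplicon_sex} and \code{concordant}.
#' @export
verifySexByYExpression <- function(tpm, yGeneIds, threshold = 1,
                                   ampliconSex = NULL) {
    if (is(tpm, "SummarizedExperiment")) tpm <- assay(tpm, "tpm")
    hit <- intersect(yGeneIds, rownames(tpm))
    if (length(hit) == 0)
        stop("none of the Y gene ids are present in the expression matrix")
    ymean <- colMeans(tpm[hit, , drop = FALSE])
    out <- data.frame(sample_id = colnames(tpm), mean_y_tpm = ymean,
                      expression_sex = ifelse(ymean > threshold,
                                              "male", "female"),
                      row.names = NULL)
    if (!is.null(ampliconSex)) {
        out$amplicon_sex <- as.character(ampliconSex)
        out$concordant <- out$expression_sex == out$amplicon_sex
    }
    out
}

#' Pearson chi-square test of a 1:1 sex ratio
#'
#' Tests observed male/female counts against the 1:1 expectation with the
#' Pearson goodness-of-fit statistic (df = 1, no continuity correction):
#' \eqn{\chi^2 = \sum (O - E)^2 / E} with \eqn{E = (n_m + n_f)/2} for each
#' sex, which reduces to \eqn{(n_m - n_f)^2 / (n_m + n_f)}.
#'
#' @param nMale,nFemale non-negative counts of sexed embryos.
#' @return A data.frame with \code{n_male}, \code{n_female}, \code{ratio}
#'   (male:female), \code{chi2}, \code{df} and \code{p}.
#' @examples
#' sexRatioTest(107, 48)   # ratio 2.23, p ~ 2.15e-06
#' sexRatioTest(8, 4)      # ratio 2, p = 0.25
#' @export
sexRatioTest <- function(nMale, nFemale) {
    if (length(nMale) != 1 || length(nFemale) != 1 ||
        nMale < 0 || nFemale < 0)
        stop("counts must be single non-negative numbers")
    n <- nMale + nFemale
    if (n == 0) stop("at least one sexed embryo is required")
    chi2 <- (nMale - nFemale)^2 / n
    data.frame(n_male = nMale, n_female = nFemale,
               ratio = if (nFemale > 0) nMale / nFemale else Inf,
               chi2 = chi2, df = 1L,
               p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Stage-wise sex-ratio table for a sexed cohort
#'
#' Applies \code{\link{sexRatioTest}} within each day x stage stratum of a
#' cohort table; embryos with undetermined sex are excluded.
#'
#' @param cohort data.frame with columns \code{day}, \code{stage} and
#'   \code{called_sex} (as produced by \code{\link{generateCohort}}).
#' @return data.frame, one row per day/stage with counts, ratio, chi2, p.
#' @export
stageSexRatios <- function(cohort) {
    keep <- cohort$called_sex %in% c("male", "female")
    cohort <- cohort[keep, , drop = FALSE]
    strata <- unique(cohort[, c("day", "stage")])
    strata <- strata[order(strata$day, strata$stage), , drop = FALSE]
    res <- lapply(seq_len(nrow(strata)), function(i) {
        sub <- cohort[cohort$day == strata$day[i] &
                      cohort$stage == strata$stage[i], ]
        cbind(strata[i, , drop = FALSE],
              sexRatioTest(sum(sub$called_sex == "male"),
                           sum(sub$called_sex == "female")))
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}
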