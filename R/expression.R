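#' Transcripts-per-million normalization
#'
#' Per sample, counts are first divided by feature length in kilobases
#' (reads per kilobase), then scaled so each column sums to one million.
#' Samples with all-zero counts yield an all-zero column (with a warning)
#' rather than an error.
#'
#' @param counts count matrix (features x samples) or a
#'   \linkS4class{SexExperiment}.
#' @param lengths feature lengths in bp (ignored for a SexExperiment, which
#'   carries its own).
#' @return For a matrix input, the TPM matrix; for a SexExperiment, the same
#'   object with a \code{tpm} assay added.
#' @examples
#' computeTPM(matrix(c(100, 100), 2, 1), lengths = c(1000, 2000))
#' @export
setGeneric("computeTPM", function(counts, lengths) standardGeneric("computeTPM"))

#' @rdname computeTPM
#' @export
setMethod("computeTPM", "matrix", function(counts, lengths) {
    if (any(lengths <= 0)) stop("feature lengths must be > 0")
    if (length(lengths) != nrow(counts))
        stop("'lengths' must have one entry per feature")
    rate <- counts / (lengths / 1000)
    tot <- colSums(rate)
    zero <- tot == 0
    if (any(zero)) {
        warning(sum(zero), " sample(s) have all-zero counts; ",
                "their TPM columns are zero")
        tot[zero] <- 1
    }
    sweep(rate, 2, tot, "/") * 1e6
})

#' @rdname computeTPM
#' @export
setMethod("computeTPM", "SexExperiment", function(counts, lengths) {
    tpm <- computeTPM(assay(counts, "counts"), featureLengths(counts))
    assays(counts)$tpm <- tpm
    counts
})

#' Median-of-ratios size factors
#'
#' Library-size normalization in the style of count-based DE frameworks:
#' each sample's factor is the median across features of the ratio of its
#' count to the feature's geometric mean across samples (features with any
#' zero are excluded from the reference).
#'
#' @param counts count matrix (features x samples).
#' @return numeric vector of size factors, one per sample.
#' @export
sizeFactors <- function(counts) {
    loggeo <- rowMeans(log(counts))
    use <- is.finite(loggeo)
    if (!any(use))
        stop("no feature is expressed in every sample; cannot compute ",
             "median-of-ratios size factors")
    sf <- apply(counts[use, , drop = FALSE], 2, function(x)
        exp(stats::median(log(x) - loggeo[use])))
    sf
}

#' Sex-biased differential expression (negative-binomial GLM)
#'
#' Per-gene negative-binomial generalized linear model of counts on sex, with
#' an optional batch covariate (e.g. embryo collection week), median-of-ratios
#' size factors as offsets, a method-of-moments dispersion per gene (no
#' shrinkage), and a Wald test on the sex coefficient. This is a deliberately
#' self-contained approximation of the shrinkage-based DE frameworks; its
#' gene-level calls are calibrated on simulated data, not tuned to any
#' published DEG count. Genes with all-zero counts are excluded and reported.
#'
#' A gene is flagged as a DEG when |fold change| > \code{fcThreshold} AND
#' FDR < \code{fdrThreshold}, both strict, with Benjamini-Hochberg FDR.
#'
#' @param se a \linkS4class{SexExperiment} (uses \code{sex} and, when present,
#'   \code{batch} from colData).
#' @param fcThreshold linear fold-change threshold (default 1.5).
#' @param fdrThreshold FDR threshold (default 0.1).
#' @param minDispersion floor on the method-of-moments dispersion.
#' @return data.frame with one row per tested gene: \code{gene_id},
#'   \code{base_mean}, \code{log2_fold_change} (male vs female), \code{se},
#'   \code{p}, \code{fdr}, \code{is_deg}, \code{direction}. Excluded all-zero
#'   genes are listed in \code{attr(,"excluded")}.
#' @export
differentialExpression <- function(se, fcThreshold = 1.5, fdrThreshold = 0.1,
                                   minDispersion = 1e-8) {
    counts <- assay(se, "counts")
    sex <- factor(sampleSex(se), levels = c("female", "male"))
    if (any(table(sex) < 2))
        stop("at least two samples per sex are required")
    batch <- colData(se)$batch
    zero <- rowSums(counts) == 0
    excluded <- rownames(counts)[zero]
    counts <- counts[!zero, , drop = FALSE]

    sf <- sizeFactors(counts)
    norm <- sweep(counts, 2, sf, "/")
    baseMean <- rowMeans(norm)

    # method-of-moments dispersion from within-sex moments of normalized
    # counts, floored; the floor keeps near-Poisson genes fittable
    disp <- vapply(seq_len(nrow(norm)), function(i) {
        x <- split(norm[i, ], sex)
        mu <- mean(norm[i, ])
        v <- mean(vapply(x, stats::var, 0), na.rm = TRUE)
        max((v - mu) / mu^2, minDispersion)
    }, 0)
    disp <- pmin(disp, 10)

    hasBatch <- !is.null(batch) && length(unique(batch)) > 1
    design <- if (hasBatch)
        stats::model.matrix(~ sex + factor(batch))
    else stats::model.matrix(~ sex)
    off <- log(sf)

    fit1 <- function(i) {
        fam <- MASS::negative.binomial(theta = 1 / disp[i])
        f <- tryCatch(suppressWarnings(
            stats::glm.fit(design, counts[i, ], family = fam, offset = off)),
            error = function(e) NULL)
        if (is.null(f) || !f$converged && f$iter == 0)
            return(c(NA_real_, NA_real_))
        cf <- f$coefficients["sexmale"]
        # Wald SE from the unscaled covariance of the IRLS fit
        w <- f$weights
        XtWX <- crossprod(design * sqrt(w))
        cov <- tryCatch(solve(XtWX), error = function(e) NULL)
        if (is.null(cov)) return(c(cf, NA_real_))
        c(cf, sqrt(cov["sexmale", "sexmale"]))
    }
    est <- t(vapply(seq_len(nrow(counts)), fit1, c(0, 0)))
    log2fc <- est[, 1] / log(2)
    z <- est[, 1] / est[, 2]
    p <- 2 * stats::pnorm(-abs(z))
    fdr <- stats::p.adjust(p, method = "BH")
    res <- data.frame(gene_id = rownames(counts), base_mean = baseMean,
                      log2_fold_change = log2fc, se = est[, 2] / log(2),
                      p = p, fdr = fdr, row.names = NULL)
    # strict FC > threshold, with a guard so a fold change numerically
    # equal to the threshold is never flagged
    res$is_deg <- !is.na(p) &
        abs(res$log2_fold_change) - log2(fcThreshold) > 1e-8 &
        res$fdr < fdrThreshold
    res$direction <- ifelse(!res$is_deg, "none",
                            ifelse(res$log2_fold_change > 0,
                                   "male_biased", "female_biased"))
    attr(res, "excluded") <- excluded
    res
}

#' Gene-group enrichment of a DEG set (Fisher exact)
#'
#' For each gene group (e.g. protein-coding, TF, TF cofactor, autosomal, X, Y)
#' a two-sided Fisher exact test on the 2x2 table of DEG membership x group
#' membership, against the supplied background universe. Direction is read
#' off the odds ratio (over- vs under-represented among DEGs).
#'
#' @param degIds character vector of DEG gene ids (subset of background).
#' @param geneGroups named list of character vectors of gene ids.
#' @param backgroundIds the gene universe.
#' @param alpha significance level for the flag (default 0.01).
#' @return data.frame per group: counts, odds ratio, direction, p,
#'   significant.
#' @export
groupEnrichment <- function(degIds, geneGroups, backgroundIds, alpha = 0.01) {
    if (!all(degIds %in% backgroundIds))
        stop("degIds must be a subset of backgroundIds")
    degIds <- unique(degIds)
    backgroundIds <- unique(backgroundIds)
    res <- lapply(names(geneGroups), function(g) {
        grp <- intersect(geneGroups[[g]], backgroundIds)
        if (length(grp) == 0) {
            warning("group '", g, "' has no members in the background; skipped")
            return(NULL)
        }
        a <- sum(degIds %in% grp)
        b <- length(degIds) - a
        c_ <- length(setdiff(grp, degIds))
        d <- length(backgroundIds) - a - b - c_
        ft <- stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))
        data.frame(group = g, deg_in_group = a, deg_total = length(degIds),
                   group_size = length(grp),
                   background_size = length(backgroundIds),
                   odds_ratio = unname(ft$estimate),
                   direction = if (ft$estimate >= 1) "over" else "under",
                   p = ft$p.value, significant = ft$p.value < alpha)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Relative expression by the 2^-ddCt method
#'
#' Classic qPCR relative quantification against one or more reference genes
#' and a control condition: \eqn{\Delta Ct = Ct_{target} - mean(Ct_{refs})}
#' within each condition, and fold change
#' \eqn{2^{-(\Delta Ct_{case} - \Delta Ct_{control})}}. Reference Cts are
#' aggregated by arithmetic mean (the geometric mean of the linear-scale
#' quantities).
#'
#' @param ctTarget,ctTargetControl Ct of the target gene in case / control.
#' @param ctReferences,ctReferencesControl numeric vectors of reference-gene
#'   Cts in case / control.
#' @return the relative fold change (case vs control).
#' @examples
#' ddctFoldChange(20, c(20, 22), 21, c(20, 22))  # ddCt = -1 -> fold 2
#' @export
ddctFoldChange <- function(ctTarget, ctReferences,
                           ctTargetControl, ctReferencesControl) {
    stopifnot(all(is.finite(c(ctTarget, ctReferences,
                              ctTargetControl, ctReferencesControl))))
    dctCase <- ctTarget - mean(ctReferences)
    dctCtrl <- ctTargetControl - mean(ctReferencesControl)
    2^(-(dctCase - dctCtrl))
}
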