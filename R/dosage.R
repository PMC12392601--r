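#' X:autosome expression ratio
#'
#' Per-gene expression is the mean TPM across the chosen group's samples;
#' genes are filtered to a category -- \code{"expressed"} (mean TPM > 1),
#' \code{"deg"} or \code{"non_deg"} (from a DE result) -- optionally dropping
#' annotated paralogs, and the ratio of the median over X-linked genes to the
#' median over autosomal genes is returned. Y-linked genes never enter either
#' stratum. A ratio near 1 indicates complete compensatory upregulation of
#' the single active X; near 0.5, none.
#'
#' @param tpm TPM matrix (genes x samples) or SexExperiment with a
#'   \code{tpm} assay.
#' @param geneInfo data.frame with \code{gene_id}, \code{chrom_class}
#'   (\code{"autosome"/"X"/"Y"}) and logical \code{is_paralog}.
#' @param group \code{"female"} or \code{"male"} (requires \code{sampleSex}),
#'   or \code{NULL} to use all samples.
#' @param sampleSex per-sample sex labels (taken from the object for a
#'   SexExperiment).
#' @param category \code{"expressed"}, \code{"deg"} or \code{"non_deg"}.
#' @param degIds gene ids called DEG (required for deg/non_deg categories).
#' @param excludeParalogs drop genes flagged \code{is_paralog}.
#' @param tpmCutoff expressed-gene cutoff (default 1, strict >).
#' @param minGenes smallest admissible stratum (default 2).
#' @return list with \code{ratio}, \code{n_x}, \code{n_a}, and the per-gene
#'   expression vectors \code{x} and \code{a}.
#' @export
xaRatio <- function(tpm, geneInfo, group = NULL, sampleSex = NULL,
                    category = c("expressed", "deg", "non_deg"),
                    degIds = NULL, excludeParalogs = FALSE,
                    tpmCutoff = 1, minGenes = 2) {
    category <- match.arg(category)
    if (is(tpm, "SummarizedExperiment")) {
        if (is.null(sampleSex)) sampleSex <- sampleSex(tpm)
        tpm <- assay(tpm, "tpm")
    }
    if (!is.null(group)) {
        if (is.null(sampleSex))
            stop("'sampleSex' is required when selecting a group")
        tpm <- tpm[, sampleSex == group, drop = FALSE]
        if (ncol(tpm) == 0) stop("no samples in group '", group, "'")
    }
    expr <- rowMeans(tpm)
    gi <- geneInfo[match(names(expr), geneInfo$gene_id), ]
    keep <- !is.na(gi$chrom_class) & gi$chrom_class %in% c("autosome", "X")
    if (excludeParalogs) keep <- keep & !gi$is_paralog
    keep <- keep & switch(category,
        expressed = expr > tpmCutoff,
        deg = names(expr) %in% degIds,
        non_deg = !(names(expr) %in% degIds) & expr > tpmCutoff)
    x <- expr[keep & gi$chrom_class == "X"]
    a <- expr[keep & gi$chrom_class == "autosome"]
    if (length(x) < minGenes)
        stop("X stratum has fewer than ", minGenes, " genes")
    if (length(a) < minGenes)
        stop("autosomal stratum has fewer than ", minGenes, " genes")
    list(ratio = stats::median(x) / stats::median(a),
         n_x = length(x), n_a = length(a), x = x, a = a)
}

#' Stratified bootstrap confidence interval for the X:A ratio
#'
#' Genes are resampled with replacement within the X stratum and within the
#' autosomal stratum independently; the median ratio is recomputed per
#' replicate and a percentile interval is reported. Deterministic under
#' \code{seed}.
#'
#' @inheritParams xaRatio
#' @param nBoot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @param ... passed on to \code{\link{xaRatio}}.
#' @return data.frame with \code{group}, \code{category},
#'   \code{paralogs_excluded}, \code{xa_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{n_x}, \code{n_a}, \code{n_boot}.
#' @export
xaBootstrapCI <- function(tpm, geneInfo, group = NULL, sampleSex = NULL,
                          category = "expressed", degIds = NULL,
                          excludeParalogs = FALSE, nBoot = 1000,
                          seed = 1, conf = 0.95, ...) {
    if (nBoot < 1) stop("nBoot must be >= 1")
    pt <- xaRatio(tpm, geneInfo, group = group, sampleSex = sampleSex,
                  category = category, degIds = degIds,
                  excludeParalogs = excludeParalogs, ...)
    set.seed(seed)
    reps <- vapply(seq_len(nBoot), function(i) {
        xb <- sample(pt$x, length(pt$x), replace = TRUE)
        ab <- sample(pt$a, length(pt$a), replace = TRUE)
        stats::median(xb) / stats::median(ab)
    }, 0)
    qs <- stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          names = FALSE, type = 7)
    data.frame(group = if (is.null(group)) "all" else group,
               category = category, paralogs_excluded = excludeParalogs,
               xa_ratio = pt$ratio, ci_low = qs[1], ci_high = qs[2],
               n_x = pt$n_x, n_a = pt$n_a, n_boot = nBoot)
}

#' Gene density along a chromosome in fixed windows
#'
#' Tiles \code{[0, chromLength)} with windows of the given width (default
#' 1 Mb); each gene is assigned to the window containing its start
#' coordinate (0-based). Runs of consecutive empty windows are flagged, a
#' quick screen for gene deserts / PAR-like gaps.
#'
#' @param positions 0-based gene start coordinates on the chromosome.
#' @param chromLength chromosome length in bp.
#' @param window window width in bp (default 1e6).
#' @return data.frame per window: \code{window_start}, \code{window_end},
#'   \code{count}; empty-window runs in \code{attr(,"empty_runs")}.
#' @examples
#' degWindowDensity(c(5e5, 1.5e6, 1.6e6), 2e6)
#' @export
degWindowDensity <- function(positions, chromLength, window = 1e6) {
    if (length(positions) && (any(positions < 0) ||
                              any(positions >= chromLength)))
        stop("positions must lie in [0, chromLength)")
    nw <- ceiling(chromLength / window)
    idx <- floor(positions / window) + 1
    counts <- tabulate(idx, nbins = nw)
    out <- data.frame(window_start = (seq_len(nw) - 1) * window,
                      window_end = pmin(seq_len(nw) * window, chromLength),
                      count = counts)
    r <- rle(counts == 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    attr(out, "empty_runs") <- data.frame(
        first_window = starts[r$values], last_window = ends[r$values])
    out
}
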