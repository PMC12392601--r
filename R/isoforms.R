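# Intron chains are encoded as "donorStart-acceptorEnd" junction strings in
# genomic coordinates; two chains match iff their junction sequences match.
.chainKey <- function(starts, ends) paste(starts, ends, sep = "-")

# reference index: per transcript the intron chain, per chrom/strand the
# known splice sites and junctions
.referenceIndex <- function(annotation) {
    ex <- exonsBy(annotation)
    tx <- names(ex)
    chains <- lapply(tx, function(t) {
        e <- ex[[t]][order(start(ex[[t]]))]
        if (length(e) < 2) return(NULL)
        list(starts = end(e)[-length(e)] + 1L, ends = start(e)[-1] - 1L)
    })
    names(chains) <- tx
    g <- txToGene(annotation)
    key <- vapply(tx, function(t) {
        e <- ex[[t]]
        paste(as.character(seqnames(e))[1], as.character(strand(e))[1])
    }, "")
    list(exons = ex, chains = chains, txGene = g, key = key)
}

#' Classify long-read isoform chains against a reference annotation
#'
#' SQANTI-style categories by intron-chain comparison. For a multi-exonic
#' chain on the strand of an overlapping reference gene: \code{FSM} when the
#' intron chain equals a reference transcript's chain exactly; \code{ISM}
#' when it equals a consecutive sub-chain of one (the 5'-degradation
#' pattern); \code{NIC} when every splice site is annotated but the junction
#' combination is novel; \code{NNC} when at least one splice site is absent
#' from the reference. Chains overlapping no same-strand gene are
#' \code{antisense} (gene on the opposite strand) or \code{intergenic};
#' chains spanning two or more non-overlapping same-strand genes are
#' \code{fusion}; mono-exonic chains are \code{FSM} when inside a mono-exonic
#' reference transcript of the same strand and otherwise
#' \code{genic_genomic} (within a gene) or \code{intergenic}. Gene-overlap
#' categories take precedence over splice categories, and FSM over ISM.
#' Splice-site identity is exact coordinate match by default; \code{wobble}
#' allows +/- that many bases.
#'
#' @param chains data.frame with \code{isoform_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} and list-columns
#'   \code{intron_starts}, \code{intron_ends} (empty integer vectors for
#'   mono-exonic chains).
#' @param annotation a \linkS4class{TxAnnotation}.
#' @param wobble splice-site matching window in bases (default 0, exact).
#' @return data.frame: \code{isoform_id}, \code{category},
#'   \code{associated_gene} (NA for intergenic),
#'   \code{associated_transcript} (FSM/ISM only).
#' @export
classifyIsoforms <- function(chains, annotation, wobble = 0) {
    idx <- .referenceIndex(annotation)
    genes <- geneInfo(annotation)
    res <- lapply(seq_len(nrow(chains)), function(i) {
        ch <- chains[i, ]
        istarts <- ch$intron_starts[[1]]
        iends <- ch$intron_ends[[1]]
        if (length(istarts) &&
            (is.unsorted(istarts, strictly = TRUE) ||
             any(iends < istarts) ||
             any(istarts[-1] <= iends[-length(iends)])))
            stop("malformed intron chain for '", ch$isoform_id, "'")
        gOv <- genes[genes$chrom == ch$chrom &
                     genes$start <= ch$end & genes$end >= ch$start, ]
        same <- gOv[gOv$strand == ch$strand, ]
        base <- data.frame(isoform_id = ch$isoform_id, category = NA,
                           associated_gene = NA_character_,
                           associated_transcript = NA_character_)
        if (nrow(same) == 0) {
            base$category <- if (nrow(gOv) > 0) "antisense" else "intergenic"
            if (nrow(gOv) > 0) base$associated_gene <- gOv$gene_id[1]
            return(base)
        }
        # fusion: the chain spans >= 2 same-strand genes with disjoint spans
        if (nrow(same) >= 2) {
            o <- order(same$start)
            disjoint <- all(same$end[o][-nrow(same)] < same$start[o][-1])
            if (disjoint) {
                base$category <- "fusion"
                base$associated_gene <- paste(same$gene_id[o], collapse = "+")
                return(base)
            }
        }
        base$associated_gene <- same$gene_id[1]
        key <- paste(ch$chrom, ch$strand)
        txHere <- names(idx$key)[idx$key == key]
        if (length(istarts) == 0) {
            for (t in txHere) {
                e <- idx$exons[[t]]
                if (length(e) == 1 && start(e) <= ch$start &&
                    end(e) >= ch$end &&
                    idx$txGene[t] %in% same$gene_id) {
                    base$category <- "FSM"
                    base$associated_gene <- unname(idx$txGene[t])
                    base$associated_transcript <- t
                    return(base)
                }
            }
            base$category <- "genic_genomic"
            return(base)
        }
        qKey <- .chainKey(istarts, iends)
        siteMatch <- function(x, sites)
            vapply(x, function(p) any(abs(sites - p) <= wobble), TRUE)
        refStarts <- integer(); refEnds <- integer()
        for (t in txHere) {
            rc <- idx$chains[[t]]
            if (is.null(rc)) next
            refStarts <- c(refStarts, rc$starts)
            refEnds <- c(refEnds, rc$ends)
            rKey <- .chainKey(rc$starts, rc$ends)
            if (length(rKey) == length(qKey) && all(rKey == qKey)) {
                base$category <- "FSM"
                base$associated_gene <- unname(idx$txGene[t])
                base$associated_transcript <- t
                return(base)
            }
        }
        for (t in txHere) {  # ISM second: FSM has precedence
            rc <- idx$chains[[t]]
            if (is.null(rc) || length(rc$starts) <= length(qKey)) next
            rKey <- .chainKey(rc$starts, rc$ends)
            for (off in 0:(length(rKey) - length(qKey))) {
                if (all(rKey[seq_along(qKey) + off] == qKey)) {
                    base$category <- "ISM"
                    base$associated_gene <- unname(idx$txGene[t])
                    base$associated_transcript <- t
                    return(base)
                }
            }
        }
        known <- all(siteMatch(istarts, refStarts)) &&
            all(siteMatch(iends, refEnds))
        base$category <- if (known) "NIC" else "NNC"
        base
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
}

#' Sex-biased isoform expression test
#'
#' Per-isoform two-sided Wilcoxon rank-sum test on size-factor-normalized
#' counts between sexes, with Benjamini-Hochberg q-values; a deliberately
#' assumption-light stand-in for inferential-replicate methods. Isoforms
#' detect sex-biased transcript usage that gene-level aggregation can
#' cancel out (isoform switching).
#'
#' @param se isoform-level \linkS4class{SexExperiment}.
#' @param qThreshold bias-call threshold (default 0.05, strict <).
#' @param isoformGene optional named character mapping isoform id -> gene id
#'   (e.g. from \code{\link{classifyIsoforms}}); unmapped isoforms are
#'   reported.
#' @return data.frame per isoform: \code{isoform_id}, \code{gene_id},
#'   \code{log2_fold_change} (male vs female, of normalized means), \code{p},
#'   \code{q}, \code{is_biased}, \code{direction}; unmapped isoforms in
#'   \code{attr(,"unmapped")}.
#' @export
differentialIsoformTest <- function(se, qThreshold = 0.05,
                                    isoformGene = NULL) {
    counts <- assay(se, "counts")
    sex <- factor(sampleSex(se), levels = c("female", "male"))
    if (any(table(sex) < 2))
        stop("at least two samples per sex are required")
    sf <- tryCatch(sizeFactors(counts),
                   error = function(e) colSums(counts) /
                       mean(colSums(counts)))
    norm <- sweep(counts, 2, sf, "/")
    p <- apply(norm, 1, function(x) {
        if (all(x == x[1])) return(NA_real_)
        suppressWarnings(stats::wilcox.test(x[sex == "male"],
                                            x[sex == "female"])$p.value)
    })
    q <- stats::p.adjust(p, method = "BH")
    mF <- rowMeans(norm[, sex == "female", drop = FALSE])
    mM <- rowMeans(norm[, sex == "male", drop = FALSE])
    lfc <- log2((mM + 0.5) / (mF + 0.5))
    gene <- if (!is.null(isoformGene))
        unname(isoformGene[rownames(counts)]) else NA_character_
    res <- data.frame(isoform_id = rownames(counts), gene_id = gene,
                      log2_fold_change = lfc, p = p, q = q,
                      is_biased = !is.na(q) & q < qThreshold,
                      row.names = NULL)
    res$direction <- ifelse(!res$is_biased, "none",
                            ifelse(lfc > 0, "male_biased", "female_biased"))
    attr(res, "unmapped") <-
        res$isoform_id[!is.null(isoformGene) & is.na(res$gene_id)]
    res
}

#' Exclusive intersections of DEG / splicing / isoform gene sets
#'
#' UpSet-style partition of three gene-id sets into the seven disjoint
#' membership patterns; the pattern counts sum to the size of the union.
#'
#' @param degGenes,dsgGenes,deiGenes character vectors of gene ids
#'   (differentially expressed, differentially spliced, differential
#'   isoform usage).
#' @return data.frame with one row per pattern (\code{deg}, \code{dsg},
#'   \code{dei} logical flags and \code{count}), plus set sizes in
#'   \code{attr(,"set_sizes")}.
#' @export
integrateGeneSets <- function(degGenes, dsgGenes, deiGenes) {
    degGenes <- unique(degGenes); dsgGenes <- unique(dsgGenes)
    deiGenes <- unique(deiGenes)
    all_ <- unique(c(degGenes, dsgGenes, deiGenes))
    m <- cbind(deg = all_ %in% degGenes, dsg = all_ %in% dsgGenes,
               dei = all_ %in% deiGenes)
    pat <- expand.grid(deg = c(TRUE, FALSE), dsg = c(TRUE, FALSE),
                       dei = c(TRUE, FALSE))
    pat <- pat[rowSums(pat) > 0, ]
    pat$count <- apply(pat, 1, function(p)
        sum(m[, "deg"] == p["deg"] & m[, "dsg"] == p["dsg"] &
            m[, "dei"] == p["dei"]))
    rownames(pat) <- NULL
    attr(pat, "set_sizes") <- c(deg = length(degGenes),
                                dsg = length(dsgGenes),
                                dei = length(deiGenes))
    pat
}
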