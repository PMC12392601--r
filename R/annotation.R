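#' @importFrom GenomicRanges GRanges GRangesList seqnames strand start end
#'   width reduce findOverlaps
#' @importFrom IRanges IRanges
NULL

#' TxAnnotation: gene models for a (toy or real) genome
#'
#' Gene-level metadata plus per-transcript exon and CDS structures. Exons and
#' CDS are \code{GRangesList}s named by transcript id, each element sorted by
#' genomic coordinate and non-overlapping; coordinates are 1-based inclusive
#' (the GTF convention). Gene metadata records the chromosome class
#' (autosome/X/Y) and the flags used downstream: biotype, transcription
#' factor, TF cofactor, paralog, X-inactivation escapee.
#'
#' @slot genes DataFrame: \code{gene_id}, \code{chrom}, \code{strand},
#'   \code{start}, \code{end}, \code{chrom_class}, \code{biotype},
#'   \code{is_tf}, \code{is_tf_cofactor}, \code{is_paralog},
#'   \code{is_escapee}.
#' @slot exons,cds GRangesList named by transcript id (cds may omit
#'   non-coding transcripts).
#' @slot txGene named character: transcript id -> gene id.
#' @export
setClass("TxAnnotation",
    representation(genes = "DataFrame", exons = "GRangesList",
                   cds = "GRangesList", txGene = "character"))

setValidity("TxAnnotation", function(object) {
    msg <- character()
    if (!all(names(object@cds) %in% names(object@exons)))
        msg <- c(msg, "every CDS transcript needs an exon structure")
    if (!all(names(object@exons) %in% names(object@txGene)))
        msg <- c(msg, "every transcript must map to a gene")
    if (length(object@cds)) {
        w <- sum(width(object@cds))
        if (any(w %% 3 != 0))
            msg <- c(msg, "total CDS length must be divisible by 3")
    }
    if (length(object@cds)) {
        ucds <- unlist(object@cds, use.names = TRUE)
        uex <- unlist(object@exons, use.names = TRUE)
        ov <- findOverlaps(ucds, uex, type = "within")
        sameTx <- names(ucds)[S4Vectors::queryHits(ov)] ==
            names(uex)[S4Vectors::subjectHits(ov)]
        covered <- unique(S4Vectors::queryHits(ov)[sameTx])
        if (length(covered) < length(ucds))
            msg <- c(msg, "CDS intervals must lie within exons")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a TxAnnotation
#' @param genes,exons,cds,txGene see \linkS4class{TxAnnotation}.
#' @export
TxAnnotation <- function(genes, exons, cds, txGene) {
    new("TxAnnotation", genes = as(genes, "DataFrame"),
        exons = exons, cds = cds, txGene = txGene)
}

setMethod("show", "TxAnnotation", function(object) {
    cat("TxAnnotation:", nrow(object@genes), "genes,",
        length(object@exons), "transcripts (",
        length(object@cds), "coding ) on",
        length(unique(object@genes$chrom)), "chromosomes\n")
})

#' @rdname TxAnnotation
#' @param object a TxAnnotation.
#' @export
geneInfo <- function(object) object@genes

#' @rdname TxAnnotation
#' @export
exonsBy <- function(object) object@exons

#' @rdname TxAnnotation
#' @export
cdsBy <- function(object) object@cds

#' @rdname TxAnnotation
#' @export
txToGene <- function(object) object@txGene

#' Strand of a transcript
#' @param object a TxAnnotation.
#' @param tx transcript id.
#' @export
txStrand <- function(object, tx) {
    as.character(strand(object@exons[[tx]]))[1]
}
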