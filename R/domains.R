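#' @importFrom Biostrings DNAStringSet DNAString reverseComplement translate
#'   subseq writeXStringSet readDNAStringSet AAStringSet xscat
NULL

#' Translate the CDS of a transcript model
#'
#' Concatenates the CDS intervals in transcription order (ascending genomic
#' coordinate on the plus strand, descending with reverse-complement on the
#' minus strand) and translates with the standard genetic code. A trailing
#' stop codon is dropped from the returned protein; an internal stop is an
#' error, as is a CDS whose length is not a multiple of 3.
#'
#' @param annotation a \linkS4class{TxAnnotation}.
#' @param tx transcript id with a CDS.
#' @param genome a named \code{DNAStringSet} of chromosome sequences.
#' @return an \code{AAString} protein sequence.
#' @export
translateCDS <- function(annotation, tx, genome) {
    cds <- cdsBy(annotation)[[tx]]
    if (is.null(cds) || length(cds) == 0)
        stop("transcript '", tx, "' has no CDS")
    chrom <- as.character(seqnames(cds))[1]
    if (!chrom %in% names(genome))
        stop("no sequence for chromosome '", chrom, "'")
    cds <- cds[order(start(cds))]
    pieces <- lapply(seq_along(cds), function(i)
        subseq(genome[[chrom]], start(cds)[i], end(cds)[i]))
    nt <- do.call(xscat, pieces)
    if (txStrand(annotation, tx) == "-") nt <- reverseComplement(nt)
    if (length(nt) %% 3 != 0)
        stop("CDS length of '", tx, "' is not divisible by 3")
    aa <- translate(nt)
    s <- strsplit(as.character(aa), "")[[1]]
    if (length(s) && s[length(s)] == "*") s <- s[-length(s)]
    if (any(s == "*"))
        stop("internal stop codon in CDS of '", tx, "'")
    Biostrings::AAString(paste(s, collapse = ""))
}

#' Filter PFAM-style domain hits to high confidence
#'
#' Keeps hits passing all five criteria: domain (bit) score > 10, domain
#' E-value < 0.01, full-sequence E-value < 1e-5, alignment accuracy (mean
#' posterior probability) >= 0.8, and coverage of the domain model >= 0.9.
#' Boundary semantics are exactly these: the score and E-value cuts are
#' strict, accuracy and coverage are inclusive. Hits with any missing metric
#' are rejected with reason \code{"incomplete"}.
#'
#' @param hits data.frame with columns \code{protein_id}, \code{domain_name},
#'   \code{aa_start}, \code{aa_end}, \code{domain_score},
#'   \code{domain_evalue}, \code{seq_evalue}, \code{accuracy},
#'   \code{coverage}.
#' @param minScore,maxDomainEvalue,maxSeqEvalue,minAccuracy,minCoverage the
#'   five thresholds.
#' @return the passing subset; rejected hits with a \code{reason} column in
#'   \code{attr(,"rejected")}.
#' @export
filterDomainHits <- function(hits, minScore = 10, maxDomainEvalue = 0.01,
                             maxSeqEvalue = 1e-5, minAccuracy = 0.8,
                             minCoverage = 0.9) {
    metrics <- c("domain_score", "domain_evalue", "seq_evalue",
                 "accuracy", "coverage")
    miss <- setdiff(metrics, colnames(hits))
    if (length(miss))
        stop("hits table is missing columns: ", paste(miss, collapse = ", "))
    incomplete <- Reduce(`|`, lapply(metrics, function(m) is.na(hits[[m]])))
    ok <- !incomplete &
        hits$domain_score > minScore &
        hits$domain_evalue < maxDomainEvalue &
        hits$seq_evalue < maxSeqEvalue &
        hits$accuracy >= minAccuracy &
        hits$coverage >= minCoverage
    reason <- rep(NA_character_, nrow(hits))
    reason[incomplete] <- "incomplete"
    reason[!incomplete & !ok] <- "below_threshold"
    rejected <- hits[!ok, , drop = FALSE]
    if (nrow(rejected)) rejected$reason <- reason[!ok]
    out <- hits[ok, , drop = FALSE]
    attr(out, "rejected") <- rejected
    out
}

# Genomic coordinates of the spliced CDS, in translation order (5'->3' of
# the mRNA): ascending positions for '+', descending for '-'.
.cdsPositionMap <- function(annotation, tx) {
    cds <- cdsBy(annotation)[[tx]]
    if (is.null(cds)) stop("transcript '", tx, "' has no CDS")
    cds <- cds[order(start(cds))]
    pos <- unlist(lapply(seq_along(cds), function(i)
        seq(start(cds)[i], end(cds)[i])))
    if (txStrand(annotation, tx) == "-") pos <- rev(pos)
    pos
}

#' Lift a protein (amino-acid) interval to genomic coordinates
#'
#' Amino acid \eqn{k} owns spliced-CDS nucleotides \eqn{3k-2 .. 3k} (1-based);
#' those positions map through the transcript's exon structure, strand-aware,
#' to one or more genomic intervals (more than one when the span crosses an
#' exon junction). The returned intervals are sorted and merged; their
#' total width always equals 3x the amino-acid span. The trailing stop codon
#' is not part of protein coordinates.
#'
#' @param annotation a \linkS4class{TxAnnotation}.
#' @param tx transcript id with a CDS.
#' @param aaStart,aaEnd 1-based inclusive amino-acid interval.
#' @return a \code{GRanges} of genomic intervals.
#' @export
proteinToGenomic <- function(annotation, tx, aaStart, aaEnd) {
    if (aaStart < 1 || aaEnd < aaStart)
        stop("invalid amino-acid interval")
    pos <- .cdsPositionMap(annotation, tx)
    nAA <- length(pos) %/% 3
    # the final codon is the stop when the CDS includes it
    if (aaEnd > nAA)
        stop("amino-acid interval exceeds the CDS (", nAA, " codons)")
    nt <- pos[(3 * aaStart - 2):(3 * aaEnd)]
    ir <- reduce(IRanges(start = sort(nt), width = 1))
    cds <- cdsBy(annotation)[[tx]]
    GRanges(seqnames = as.character(seqnames(cds))[1], ranges = ir,
            strand = txStrand(annotation, tx))
}

#' Call protein domains disrupted by skipped exons
#'
#' A (filtered) domain hit is affected when any genomic interval of its
#' lifted amino-acid span overlaps a significant skipped exon by at least
#' one base on the same chromosome. Hits on transcripts absent from the
#' annotation are skipped with a warning.
#'
#' @param hits filtered domain-hit table (see \code{\link{filterDomainHits}});
#'   \code{protein_id} must equal the transcript id.
#' @param annotation a \linkS4class{TxAnnotation}.
#' @param skippedExons a \code{GRanges} of significant skipped exons
#'   (metadata columns, e.g. \code{event_id} and \code{bias}, are carried
#'   through), or a data.frame with \code{chrom}, \code{exon_start},
#'   \code{exon_end} and optional \code{event_id}, \code{bias}.
#' @return data.frame, one row per (hit, overlapping event) pair:
#'   domain, transcript, gene, event, bias, plus the lifted interval span;
#'   zero rows when nothing is affected. Per-bias summary counts in
#'   \code{attr(,"summary")}.
#' @export
callDisruptedDomains <- function(hits, annotation, skippedExons) {
    if (is.data.frame(skippedExons)) {
        skippedExons <- GRanges(
            seqnames = skippedExons$chrom,
            ranges = IRanges(skippedExons$exon_start, skippedExons$exon_end),
            event_id = if (!is.null(skippedExons$event_id))
                skippedExons$event_id else NA_character_,
            bias = if (!is.null(skippedExons$bias))
                skippedExons$bias else NA_character_)
    }
    rows <- list()
    for (i in seq_len(nrow(hits))) {
        tx <- hits$protein_id[i]
        if (is.null(cdsBy(annotation)[[tx]])) {
            warning("no CDS for transcript '", tx, "'; hit skipped")
            next
        }
        gr <- proteinToGenomic(annotation, tx, hits$aa_start[i],
                               hits$aa_end[i])
        sameChr <- which(as.character(seqnames(skippedExons)) ==
                         as.character(seqnames(gr))[1])
        ov <- IRanges::findOverlaps(
            IRanges(start(gr), end(gr)),
            IRanges(start(skippedExons)[sameChr],
                    end(skippedExons)[sameChr]))
        for (j in sameChr[unique(S4Vectors::subjectHits(ov))]) {
            rows[[length(rows) + 1]] <- data.frame(
                domain_name = hits$domain_name[i], transcript_id = tx,
                gene_id = unname(txToGene(annotation)[tx]),
                event_id = skippedExons$event_id[j],
                bias = skippedExons$bias[j],
                domain_chrom = as.character(seqnames(gr))[1],
                domain_start = min(start(gr)), domain_end = max(end(gr)),
                aa_start = hits$aa_start[i], aa_end = hits$aa_end[i])
        }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        data.frame(domain_name = character(), transcript_id = character(),
                   gene_id = character(), event_id = character(),
                   bias = character(), domain_chrom = character(),
                   domain_start = integer(), domain_end = integer(),
                   aa_start = integer(), aa_end = integer())
    attr(out, "summary") <- as.data.frame(table(bias = out$bias),
                                          responseName = "n_affected")
    out
}
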