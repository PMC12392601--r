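#' @importFrom rtracklayer import export
NULL

#' Write a TxAnnotation (plus gene flags) as GTF
#'
#' Emits gene, transcript, exon and CDS features, 1-based inclusive, with
#' attributes \code{gene_id}, \code{transcript_id}, \code{gene_biotype} and
#' the custom tags \code{paralog}, \code{tf_class}, \code{escapee}.
#'
#' @param annotation a \linkS4class{TxAnnotation}.
#' @param file output path.
#' @export
writeAnnotationGTF <- function(annotation, file) {
    genes <- geneInfo(annotation)
    tfClass <- ifelse(genes$is_tf, "TF",
                      ifelse(genes$is_tf_cofactor, "TF_cofactor", "none"))
    cols <- list(chrom = character(), start = integer(), end = integer(),
                 strand = character(), type = character(),
                 gene = character(), tx = character(), phase = integer())
    gidx <- integer()
    push <- function(i, type, start, end, tx = NA_character_,
                     phase = NA_integer_) {
        n <- length(start)
        cols$chrom <<- c(cols$chrom, rep(genes$chrom[i], n))
        cols$start <<- c(cols$start, start)
        cols$end <<- c(cols$end, end)
        cols$strand <<- c(cols$strand, rep(genes$strand[i], n))
        cols$type <<- c(cols$type, rep(type, n))
        cols$gene <<- c(cols$gene, rep(genes$gene_id[i], n))
        cols$tx <<- c(cols$tx, rep(tx, n))
        cols$phase <<- c(cols$phase, rep_len(phase, n))
        gidx <<- c(gidx, rep(i, n))
    }
    for (i in seq_len(nrow(genes))) {
        tx <- genes$tx_id[i]
        e <- exonsBy(annotation)[[tx]]
        push(i, "gene", genes$start[i], genes$end[i])
        push(i, "transcript", min(start(e)), max(end(e)), tx)
        push(i, "exon", start(e), end(e), tx)
        cds <- cdsBy(annotation)[[tx]]
        if (!is.null(cds)) {
            # phase = bases of the piece's first codon already emitted,
            # counting pieces in transcription (5'->3') order
            w <- end(cds) - start(cds) + 1L
            before <- if (genes$strand[i] == "+")
                c(0L, cumsum(w)[-length(w)]) else sum(w) - cumsum(w)
            ph <- (3L - before %% 3L) %% 3L
            push(i, "CDS", start(cds), end(cds), tx, ph)
        }
    }
    gr <- GRanges(cols$chrom, IRanges(cols$start, cols$end),
                  strand = cols$strand, type = cols$type,
                  phase = cols$phase,
                  gene_id = cols$gene, transcript_id = cols$tx,
                  gene_biotype = genes$biotype[gidx],
                  paralog = tolower(genes$is_paralog[gidx]),
                  tf_class = tfClass[gidx],
                  escapee = tolower(genes$is_escapee[gidx]))
    export(gr, file, format = "gtf")
    invisible(file)
}

#' Read a GTF written by \code{\link{writeAnnotationGTF}} back into a
#' TxAnnotation
#'
#' @param file GTF path.
#' @return a \linkS4class{TxAnnotation}.
#' @export
readAnnotationGTF <- function(file) {
    gr <- import(file, format = "gtf")
    gdf <- as.data.frame(gr[gr$type == "gene"])
    genes <- data.frame(
        gene_id = gdf$gene_id, chrom = as.character(gdf$seqnames),
        strand = as.character(gdf$strand), start = gdf$start, end = gdf$end,
        chrom_class = ifelse(grepl("^autosome", gdf$seqnames), "autosome",
                             as.character(gdf$seqnames)),
        biotype = gdf$gene_biotype,
        is_paralog = gdf$paralog == "true",
        is_tf = gdf$tf_class == "TF",
        is_tf_cofactor = gdf$tf_class == "TF_cofactor",
        is_escapee = gdf$escapee == "true")
    genes$is_xist_like <- genes$biotype == "lncRNA" & genes$chrom_class == "X"
    txr <- gr[gr$type == "transcript"]
    txGene <- stats::setNames(txr$gene_id, txr$transcript_id)
    genes$tx_id <- txr$transcript_id[match(genes$gene_id, txr$gene_id)]
    split_ <- function(type) {
        sub <- gr[gr$type == type]
        grl <- S4Vectors::split(GRanges(seqnames(sub),
                                        IRanges(start(sub), end(sub)),
                                        strand = strand(sub)),
                                sub$transcript_id)
        GRangesList(lapply(grl, function(x) x[order(start(x))]))
    }
    exons <- split_("exon")
    genes$tx_len <- vapply(genes$tx_id, function(t)
        sum(width(exons[[t]])), 0)
    TxAnnotation(genes, exons, split_("CDS"), txGene)
}

#' Write chromosome sequences as FASTA
#' @param genome a named \code{DNAStringSet}.
#' @param file output path.
#' @export
writeGenomeFASTA <- function(genome, file) {
    writeXStringSet(genome, file)
    invisible(file)
}

#' Read chromosome sequences from FASTA
#' @param file FASTA path.
#' @export
readGenomeFASTA <- function(file) readDNAStringSet(file)

#' Write / read a count matrix as TSV (feature, length, one column per
#' sample; sample sex on a commented header line)
#' @param se a \linkS4class{SexExperiment}.
#' @param file path.
#' @export
writeCountsTSV <- function(se, file) {
    df <- data.frame(feature_id = rownames(se),
                     length = featureLengths(se),
                     assay(se, "counts"), check.names = FALSE)
    con <- file(file, "w")
    writeLines(paste0("# sex: ", paste(sampleSex(se), collapse = ",")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
    invisible(file)
}

#' @rdname writeCountsTSV
#' @export
readCountsTSV <- function(file) {
    first <- readLines(file, n = 1)
    sex <- strsplit(sub("^# sex: ", "", first), ",")[[1]]
    df <- utils::read.delim(file, comment.char = "#", check.names = FALSE)
    counts <- as.matrix(df[, -(1:2), drop = FALSE])
    rownames(counts) <- df$feature_id
    SexExperiment(counts, lengths = df$length, sex = sex)
}

#' Write / read skipped-exon events as an rMATS-like TSV
#'
#' Columns follow the rMATS junction-count convention: per-sample inclusion
#' (IJC) and skipping (SJC) counts are comma-separated within group columns
#' (\code{SAMPLE_1} = female, \code{SAMPLE_2} = male), the skipped exon
#' start is 0-based (\code{exonStart_0base}), and \code{IncFormLen}/
#' \code{SkipFormLen} carry the effective lengths.
#'
#' @param events an \linkS4class{SEEventSet}.
#' @param file path.
#' @export
writeSEEventsTSV <- function(events, file) {
    ev <- as.data.frame(eventInfo(events))
    sex <- sampleSex(events)
    I <- inclusionCounts(events); S <- skippingCounts(events)
    cat_ <- function(m, g) apply(m[, sex == g, drop = FALSE], 1, paste,
                                 collapse = ",")
    df <- data.frame(ID = ev$event_id, GeneID = ev$gene_id,
                     transcript_id = if (!is.null(ev$transcript_id))
                         ev$transcript_id else NA,
                     chr = ev$chrom, strand = ev$strand,
                     exonStart_0base = ev$exon_start - 1L,
                     exonEnd = ev$exon_end,
                     upstreamEE = if (!is.null(ev$upstream_end))
                         ev$upstream_end else NA,
                     downstreamES = if (!is.null(ev$downstream_start))
                         ev$downstream_start else NA,
                     IJC_SAMPLE_1 = cat_(I, "female"),
                     SJC_SAMPLE_1 = cat_(S, "female"),
                     IJC_SAMPLE_2 = cat_(I, "male"),
                     SJC_SAMPLE_2 = cat_(S, "male"),
                     IncFormLen = ev$inc_len, SkipFormLen = ev$skip_len)
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeSEEventsTSV
#' @export
readSEEventsTSV <- function(file) {
    df <- utils::read.delim(file, check.names = FALSE)
    splitCounts <- function(x) {
        m <- do.call(rbind, lapply(strsplit(as.character(x), ","),
                                   as.integer))
        m
    }
    If <- splitCounts(df$IJC_SAMPLE_1); Sf <- splitCounts(df$SJC_SAMPLE_1)
    Im <- splitCounts(df$IJC_SAMPLE_2); Sm <- splitCounts(df$SJC_SAMPLE_2)
    events <- data.frame(event_id = df$ID, gene_id = df$GeneID,
                         transcript_id = df$transcript_id,
                         chrom = df$chr, strand = df$strand,
                         exon_start = df$exonStart_0base + 1L,
                         exon_end = df$exonEnd,
                         upstream_end = df$upstreamEE,
                         downstream_start = df$downstreamES,
                         inc_len = df$IncFormLen, skip_len = df$SkipFormLen)
    SEEventSet(events, cbind(If, Im), cbind(Sf, Sm),
               c(rep("female", ncol(If)), rep("male", ncol(Im))))
}

#' Write / read domain hits as a tab-separated domtblout-like table
#' @param hits domain-hit data.frame.
#' @param file path.
#' @export
writeDomainHitsTSV <- function(hits, file) {
    utils::write.table(hits, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeDomainHitsTSV
#' @export
readDomainHitsTSV <- function(file) utils::read.delim(file)

#' Write / read a cohort table as TSV
#' @param cohort cohort data.frame.
#' @param file path.
#' @export
writeCohortTSV <- function(cohort, file) {
    utils::write.table(cohort, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeCohortTSV
#' @export
readCohortTSV <- function(file) utils::read.delim(file)
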