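assay <- SummarizedExperiment::assay
rowData <- SummarizedExperiment::rowData
colData <- SummarizedExperiment::colData

# Hand-built toy annotation with an independent per-base coordinate oracle.
#
# chrT (length 1000), three genes:
#   gP (+): exons 101-130, 201-240, 301-340; CDS 111-130, 201-240, 301-312
#   gM (-): exons 501-560, 601-660;          CDS 521-560, 601-641
#   gQ (+): exons 701-760, 801-900;          CDS 711-760, 801-860
# The oracle position maps are written out explicitly (transcription order),
# independently of the package's coordinate machinery.
toyAnnotation <- function() {
    genes <- data.frame(
        gene_id = c("gP", "gM", "gQ"), chrom = "chrT",
        strand = c("+", "-", "+"),
        start = c(101L, 501L, 701L), end = c(340L, 660L, 900L),
        chrom_class = "autosome", biotype = "protein_coding",
        tx_id = c("txP", "txM", "txQ"), tx_len = c(110L, 120L, 160L),
        is_paralog = FALSE, is_tf = FALSE, is_tf_cofactor = FALSE,
        is_escapee = FALSE, is_xist_like = FALSE)
    exons <- GenomicRanges::GRangesList(
        txP = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(101, 201, 301), c(130, 240, 340)), strand = "+"),
        txM = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(501, 601), c(560, 660)), strand = "-"),
        txQ = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(701, 801), c(760, 900)), strand = "+"))
    cds <- GenomicRanges::GRangesList(
        txP = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(111, 201, 301), c(130, 240, 312)), strand = "+"),
        txM = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(521, 601), c(560, 641)), strand = "-"),
        txQ = GenomicRanges::GRanges("chrT", IRanges::IRanges(
            c(711, 801), c(760, 861)), strand = "+"))
    TxAnnotation(genes, exons, cds,
                 c(txP = "gP", txM = "gM", txQ = "gQ"))
}

# spliced-CDS -> genomic position maps, enumerated by hand (5'->3')
toyPosMaps <- function() {
    list(txP = c(111:130, 201:240, 301:312),
         txM = rev(c(521:560, 601:641)),
         txQ = c(711:760, 801:861))
}

# coding sequences and the genome carrying them; returns list(genome, coding)
# where coding[[tx]] is the designed 5'->3' CDS nucleotide string
toyGenome <- function(seed = 42) {
    set.seed(seed)
    chr <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
    maps <- toyPosMaps()
    nonstop <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T"),
                                         c("A", "C", "G", "T")), 1,
                             paste, collapse = ""),
                       c("TAA", "TAG", "TGA"))
    coding <- list()
    for (tx in names(maps)) {
        L <- length(maps[[tx]])
        cod <- c("ATG", sample(nonstop, L / 3 - 2, replace = TRUE), "TAA")
        nt <- strsplit(paste(cod, collapse = ""), "")[[1]]
        coding[[tx]] <- paste(nt, collapse = "")
        pos <- maps[[tx]]
        if (tx == "txM") nt <- chartr("ACGT", "TGCA", nt)
        chr[pos] <- nt
    }
    list(genome = Biostrings::DNAStringSet(c(
             chrT = paste(chr, collapse = ""))),
         coding = coding)
}

# exhaustive hypergeometric enumeration of the two-sided Fisher p for the
# 2x2 table rbind(c(a, b), c(c, d)) with fixed margins
enumFisherP <- function(a, b, c_, d) {
    m <- a + c_; n <- b + d; k <- a + b
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    pObs <- stats::dhyper(a, m, n, k)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# small, fast simulation setup shared by several files
quickConfig <- function(seed = 1, ...) {
    args <- utils::modifyList(list(seed = seed, nAutosomes = 2,
                                   genesPerChrom = 20, nSeEvents = 20),
                              list(...))
    do.call(simulationConfig, args)
}
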