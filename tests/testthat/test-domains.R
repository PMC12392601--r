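microAnnotation <- function(strand, exonStarts, exonEnds, cdsStarts,
                            cdsEnds, chrom = "chrU") {
    genes <- data.frame(gene_id = "g1", chrom = chrom, strand = strand,
                        start = min(exonStarts), end = max(exonEnds),
                        chrom_class = "autosome", biotype = "protein_coding",
                        tx_id = "t1",
                        tx_len = sum(exonEnds - exonStarts + 1),
                        is_paralog = FALSE, is_tf = FALSE,
                        is_tf_cofactor = FALSE, is_escapee = FALSE,
                        is_xist_like = FALSE)
    TxAnnotation(genes,
                 GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges(
                     chrom, IRanges::IRanges(exonStarts, exonEnds),
                     strand = strand)),
                 GenomicRanges::GRangesList(t1 = GenomicRanges::GRanges(
                     chrom, IRanges::IRanges(cdsStarts, cdsEnds),
                     strand = strand)),
                 c(t1 = "g1"))
}

test_that("CDS translation honors strand, frame and stop-codon rules", {
    # plus strand "ATGGCC" -> MA
    annP <- microAnnotation("+", 1, 6, 1, 6)
    gnP <- Biostrings::DNAStringSet(c(chrU = "ATGGCC"))
    expect_equal(as.character(translateCDS(annP, "t1", gnP)), "MA")
    # minus strand genomic "GGCCAT" reverse-complements to "ATGGCC" -> MA
    annM <- microAnnotation("-", 1, 6, 1, 6)
    gnM <- Biostrings::DNAStringSet(c(chrU = "GGCCAT"))
    expect_equal(as.character(translateCDS(annM, "t1", gnM)), "MA")
    # trailing stop dropped, internal stop fatal
    gnStop <- Biostrings::DNAStringSet(c(chrU = "ATGGCCTAA"))
    annS <- microAnnotation("+", 1, 9, 1, 9)
    expect_equal(as.character(translateCDS(annS, "t1", gnStop)), "MA")
    gnBad <- Biostrings::DNAStringSet(c(chrU = "ATGTAAGCC"))
    expect_error(translateCDS(annS, "t1", gnBad), "internal stop")
    # an out-of-frame CDS is rejected at annotation construction already
    expect_error(microAnnotation("+", 1, 8, 1, 8), "divisible by 3")
    expect_error(translateCDS(annP, "t1",
                              Biostrings::DNAStringSet(c(zz = "ATGGCC"))),
                 "no sequence")
})

test_that("a CDS split mid-codon translates like its concatenation", {
    gset <- toyGenome()
    ann <- toyAnnotation()
    for (tx in c("txP", "txM", "txQ")) {
        # oracle: translate the designed coding string directly
        oracle <- as.character(Biostrings::translate(
            Biostrings::DNAString(gset$coding[[tx]])))
        oracle <- sub("\\*$", "", oracle)
        expect_equal(as.character(translateCDS(ann, tx, gset$genome)),
                     oracle, info = tx)
    }
})

test_that("domain-hit filtering applies the five printed thresholds", {
    mk <- function(score = 50, dev = 1e-6, sev = 1e-10, acc = 0.95,
                   cov = 0.97)
        data.frame(protein_id = "t1", domain_name = "D", aa_start = 1,
                   aa_end = 10, domain_score = score, domain_evalue = dev,
                   seq_evalue = sev, accuracy = acc, coverage = cov)
    hits <- rbind(mk(),                      # clean pass
                  mk(score = 10),            # boundary: strict > fails
                  mk(dev = 0.01),            # boundary: strict < fails
                  mk(sev = 1e-5),            # boundary: strict < fails
                  mk(acc = 0.8),             # boundary: inclusive >= passes
                  mk(cov = 0.9),             # boundary: inclusive >= passes
                  mk(acc = NA))              # incomplete
    out <- filterDomainHits(hits)
    expect_equal(nrow(out), 3)
    expect_true(all(out$accuracy >= 0.8 & out$coverage >= 0.9, na.rm = TRUE))
    rej <- attr(out, "rejected")
    expect_equal(rej$reason[is.na(rej$accuracy)], "incomplete")
    expect_true(all(rej$reason[!is.na(rej$accuracy)] == "below_threshold"))
    # idempotent and order-independent
    again <- filterDomainHits(out)
    expect_equal(again$domain_score, out$domain_score)
    shuf <- filterDomainHits(hits[sample(nrow(hits)), ])
    expect_equal(nrow(shuf), 3)
    expect_error(filterDomainHits(hits[, -5]), "missing columns")
})

test_that("protein-to-genome lift matches the per-base enumeration oracle", {
    ann <- toyAnnotation()
    maps <- toyPosMaps()
    for (tx in names(maps)) {
        pos <- maps[[tx]]
        nAA <- length(pos) / 3 - 1      # trailing stop not liftable protein
        for (k in seq_len(nAA)) {
            gr <- proteinToGenomic(ann, tx, k, k)
            expect_setequal(
                unlist(lapply(seq_along(gr), function(j)
                    seq(GenomicRanges::start(gr)[j],
                        GenomicRanges::end(gr)[j]))),
                pos[(3 * k - 2):(3 * k)])
        }
        # spans always lift to 3x their amino-acid length
        set.seed(3)
        for (rep in 1:10) {
            a <- sample(nAA, 1); b <- a + sample.int(nAA - a + 1, 1) - 1
            gr <- proteinToGenomic(ann, tx, a, b)
            expect_equal(sum(GenomicRanges::width(gr)), 3 * (b - a + 1))
        }
        expect_error(proteinToGenomic(ann, tx, 1, nAA + 2), "exceeds")
    }
    # forced arithmetic cases: plus-strand CDS from 101, aa 1-2 -> 101..106
    annP <- microAnnotation("+", 101, 160, 101, 160)
    grP <- proteinToGenomic(annP, "t1", 1, 2)
    expect_equal(c(GenomicRanges::start(grP), GenomicRanges::end(grP)),
                 c(101, 106))
    # minus-strand CDS ending at 300: first amino acid owns 298..300
    annM <- microAnnotation("-", 201, 300, 202, 300)
    grM <- proteinToGenomic(annM, "t1", 1, 1)
    expect_equal(c(GenomicRanges::start(grM), GenomicRanges::end(grM)),
                 c(298, 300))
    # a span crossing an exon junction yields two intervals
    grJ <- proteinToGenomic(toyAnnotation(), "txP", 6, 8)
    expect_equal(length(grJ), 2)
    expect_equal(sum(GenomicRanges::width(grJ)), 9)
})

test_that("disruption calls use >=1 bp overlap with skipped exons", {
    ann <- toyAnnotation()
    hits <- data.frame(protein_id = "txP", domain_name = "D1",
                       aa_start = 6, aa_end = 8, domain_score = 50,
                       domain_evalue = 1e-6, seq_evalue = 1e-10,
                       accuracy = 0.95, coverage = 0.97)
    # aa 6..8 of txP covers genomic 126..130 + 201..204
    hit1 <- callDisruptedDomains(hits, ann, data.frame(
        chrom = "chrT", exon_start = 204, exon_end = 260,
        event_id = "E1", bias = "male_biased_inclusion"))
    expect_equal(nrow(hit1), 1)     # 1 bp overlap at 204
    hit0 <- callDisruptedDomains(hits, ann, data.frame(
        chrom = "chrT", exon_start = 205, exon_end = 260, event_id = "E1"))
    expect_equal(nrow(hit0), 0)     # adjacent but disjoint
    # upstream piece of a junction-spanning domain inside the skipped exon
    hitUp <- callDisruptedDomains(hits, ann, data.frame(
        chrom = "chrT", exon_start = 101, exon_end = 130, event_id = "E2"))
    expect_equal(hitUp$event_id, "E2")
    # wrong chromosome never overlaps
    hitChr <- callDisruptedDomains(hits, ann, data.frame(
        chrom = "chrZ", exon_start = 126, exon_end = 130, event_id = "E3"))
    expect_equal(nrow(hitChr), 0)
})

test_that("synthetic disruption labels are recovered exactly", {
    cfg <- quickConfig(seed = 301)
    aset <- generateAnnotation(cfg)
    ev <- generateSeEvents(aset, cfg)
    dh <- generateDomainHits(aset, cfg, ev$events)
    kept <- filterDomainHits(dh$hits)
    expect_setequal(kept$hit_id,
                    dh$truth$hit_id[dh$truth$passes_filter])
    info <- as.data.frame(eventInfo(ev$events))
    skipped <- data.frame(chrom = info$chrom, exon_start = info$exon_start,
                          exon_end = info$exon_end,
                          event_id = info$event_id, bias = NA)
    calls <- callDisruptedDomains(kept, aset$annotation, skipped)
    labelled <- dh$truth[!is.na(dh$truth$disrupted) &
                         dh$truth$passes_filter, ]
    # every disrupted-truth hit appears in the calls, no intact-truth hit
    for (i in seq_len(nrow(labelled))) {
        h <- kept[kept$hit_id == labelled$hit_id[i], ]
        inCalls <- any(calls$transcript_id == h$protein_id &
                       calls$aa_start == h$aa_start)
        expect_equal(inCalls, labelled$disrupted[i], info = h$hit_id)
    }
})
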