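test_that("all generators are reproducible under one seed", {
    cfg <- quickConfig(seed = 5)
    a1 <- generateAnnotation(cfg); a2 <- generateAnnotation(cfg)
    expect_identical(geneInfo(a1$annotation), geneInfo(a2$annotation))
    expect_identical(as.character(a1$genome), as.character(a2$genome))
    expect_identical(generateCohort(cfg), generateCohort(cfg))
    c1 <- generateCounts(a1, cfg); c2 <- generateCounts(a1, cfg)
    expect_identical(assay(c1$se, "counts"), assay(c2$se, "counts"))
    e1 <- generateSeEvents(a1, cfg); e2 <- generateSeEvents(a1, cfg)
    expect_identical(inclusionCounts(e1$events), inclusionCounts(e2$events))
    i1 <- generateIsoformChains(a1, cfg); i2 <- generateIsoformChains(a1, cfg)
    expect_identical(i1$truth, i2$truth)
    # a different seed actually changes the draws
    cfgB <- quickConfig(seed = 6)
    expect_false(identical(assay(c1$se, "counts"),
                           assay(generateCounts(a1, cfgB)$se, "counts")))
})

test_that("cohort emulates male-biased progression and its null", {
    # no stage advantage -> sex ratio 1 at every stage (3 sigma of 0.5)
    cfg0 <- simulationConfig(seed = 21, maleStageAdvantage = 0,
                             sexingFailureRate = 0)
    coh0 <- generateCohort(cfg0)
    n <- nrow(coh0)
    frac <- mean(coh0$true_sex == "male")
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n))
    # single-stratum design tuned to the Day-7 expanded ratio
    des <- data.frame(day = 7L, stage = "expanded", n = 155L,
                      male_frac = 107 / 155)
    cfg <- simulationConfig(seed = 22, cohortDesign = des,
                            sexingFailureRate = 0)
    coh <- generateCohort(cfg)
    m <- sum(coh$called_sex == "male")
    expect_lt(abs(m - 107), 3 * sqrt(155 * (107 / 155) * (48 / 155)))
    # sexing failures are undetermined, never miscalled
    cfgF <- simulationConfig(seed = 23, sexingFailureRate = 0.3)
    cohF <- generateCohort(cfgF)
    failed <- cohF$autosomal_amplicon == "absent"
    expect_true(all(cohF$called_sex[failed] == "undetermined"))
    expect_true(all(cohF$called_sex[!failed] == cohF$true_sex[!failed]))
    expect_error(generateCohort(simulationConfig(
        cohortDesign = data.frame(day = 7, stage = "expanded", n = 0,
                                  male_frac = 0.5))))
})

test_that("toy annotation satisfies its structural invariants", {
    cfg <- quickConfig(seed = 9, fracParalog = 0.2)
    aset <- generateAnnotation(cfg)
    ann <- aset$annotation
    genes <- geneInfo(ann)
    expect_setequal(unique(genes$chrom),
                    c("autosome_1", "autosome_2", "X", "Y"))
    expect_true(all(c("+", "-") %in% genes$strand))
    expect_equal(sum(genes$is_xist_like), 1)
    expect_equal(genes$biotype[genes$is_xist_like], "lncRNA")
    # CDS frame and containment
    w <- sum(GenomicRanges::width(cdsBy(ann)))
    expect_true(all(w %% 3 == 0))
    # exons ordered, non-overlapping
    for (tx in names(exonsBy(ann))) {
        e <- exonsBy(ann)[[tx]]
        st <- GenomicRanges::start(e); en <- GenomicRanges::end(e)
        expect_true(!is.unsorted(st, strictly = TRUE))
        expect_true(all(st[-1] > en[-length(en)]))
    }
    # paralog fraction close to the request (binomial 3 sigma)
    pfrac <- mean(genes$is_paralog)
    expect_lt(abs(pfrac - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(genes)))
    # every CDS translates to a clean protein starting with M
    gn <- aset$genome
    for (tx in head(names(cdsBy(ann)), 10)) {
        p <- as.character(translateCDS(ann, tx, gn))
        expect_true(startsWith(p, "M"))
        expect_false(grepl("\\*", p))
    }
})

test_that("counts encode the designed sex effects and close over truth", {
    cfg <- quickConfig(seed = 31)
    aset <- generateAnnotation(cfg)
    out <- generateCounts(aset, cfg)
    cnt <- assay(out$se, "counts")
    genes <- geneInfo(aset$annotation)
    sex <- sampleSex(out$se)
    # Y genes silent in females, XIST-like silent in males (leak 0)
    expect_true(all(cnt[genes$chrom_class == "Y", sex == "female"] == 0))
    expect_true(all(cnt[genes$is_xist_like, sex == "male"] == 0))
    expect_true(all(cnt[genes$is_xist_like, sex == "female"] > 0))
    # truth closure
    expect_true(all(out$truth$deg$gene_id %in% rownames(cnt)))
    expect_equal(nrow(out$truth$deg),
                 round(cfg$fracAutosomalDeg *
                       sum(genes$chrom_class == "autosome" &
                           genes$biotype == "protein_coding")))
    expect_error(generateCounts(
        list(annotation = TxAnnotation(
            genes[0, ], GenomicRanges::GRangesList(),
            GenomicRanges::GRangesList(), character())),
        cfg), "empty annotation")
})

test_that("junction counts follow the PSI allocation model", {
    # psi = 1 -> no skipping reads; psi = 0 -> no inclusion reads
    tab <- data.frame(psi_female = c(1, 0, 0.5),
                      psi_male = c(1, 0, 0.5))
    cfg <- quickConfig(seed = 41, psiTable = tab)
    aset <- generateAnnotation(cfg)
    ev <- generateSeEvents(aset, cfg)
    S <- skippingCounts(ev$events); I <- inclusionCounts(ev$events)
    expect_true(all(S[1, ] == 0))
    expect_true(all(I[2, ] == 0))
    # equal group PSI -> near-zero mean delta-PSI across many events
    cfg2 <- quickConfig(seed = 42, fracDifferentialSe = 0,
                        nSeEvents = 200, junctionDepth = 300)
    ev2 <- generateSeEvents(aset, cfg2)
    psi <- psiMatrix(ev2$events)
    sx <- sampleSex(ev2$events)
    dpsi <- rowMeans(psi[, sx == "male"]) - rowMeans(psi[, sx == "female"])
    expect_lt(abs(mean(dpsi)), 0.01)
    # event anchors reference real annotated genes and internal exons
    info <- as.data.frame(eventInfo(ev$events))
    genes <- geneInfo(aset$annotation)
    expect_true(all(info$gene_id %in% genes$gene_id))
    g <- genes[match(info$gene_id, genes$gene_id), ]
    expect_true(all(info$exon_start > g$start & info$exon_end < g$end))
    expect_error(quickConfig(psiTable = data.frame(psi_female = 1.2,
                                                   psi_male = 0.5)),
                 "PSI")
})

test_that("domain-hit generator controls each filter criterion and truth", {
    cfg <- quickConfig(seed = 51)
    aset <- generateAnnotation(cfg)
    ev <- generateSeEvents(aset, cfg)
    dh <- generateDomainHits(aset, cfg, ev$events)
    hits <- dh$hits; truth <- dh$truth
    # one hit fails exactly one criterion, for each criterion
    crit <- list(
        domain_score = function(h) h$domain_score > 10,
        domain_evalue = function(h) h$domain_evalue < 0.01,
        seq_evalue = function(h) h$seq_evalue < 1e-5,
        accuracy = function(h) h$accuracy >= 0.8,
        coverage = function(h) h$coverage >= 0.9)
    passMat <- vapply(crit, function(f) f(hits), logical(nrow(hits)))
    nFail <- rowSums(!passMat)
    for (k in seq_along(crit))
        expect_true(any(nFail == 1 & !passMat[, k]),
                    info = names(crit)[k])
    # aa intervals inside the protein
    for (i in seq_len(nrow(hits))) {
        L <- sum(GenomicRanges::width(
            cdsBy(aset$annotation)[[hits$protein_id[i]]])) / 3 - 1
        expect_gte(hits$aa_start[i], 1)
        expect_lte(hits$aa_end[i], L)
    }
    # hits constructed inside a skipped exon are labeled disrupted
    expect_true(any(truth$disrupted %in% TRUE))
    expect_true(any(truth$disrupted %in% FALSE))
})

test_that("isoform generator covers every category with closed truth", {
    cfg <- quickConfig(seed = 61)
    aset <- generateAnnotation(cfg)
    iso <- generateIsoformChains(aset, cfg)
    expect_setequal(unique(iso$truth$true_category),
                    c("FSM", "ISM", "NIC", "NNC", "intergenic", "antisense",
                      "genic_genomic", "fusion"))
    expect_setequal(iso$truth$isoform_id, iso$chains$isoform_id)
    src <- unlist(strsplit(stats::na.omit(iso$truth$source_transcript),
                           "+", fixed = TRUE))
    expect_true(all(src %in% names(exonsBy(aset$annotation))))
    expect_s4_class(iso$counts, "SexExperiment")
    expect_true(all(iso$truthCounts$isoform_id %in% iso$chains$isoform_id))
})
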