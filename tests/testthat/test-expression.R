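test_that("TPM normalization matches hand arithmetic and sums to 1e6", {
    expect_equal(computeTPM(matrix(50, 1, 1), lengths = 700)[1, 1], 1e6)
    expect_equal(computeTPM(matrix(c(10, 10), 2, 1),
                            lengths = c(500, 500))[, 1], c(5e5, 5e5))
    # length-weighting oracle: counts (100,100), lengths (1000,2000)
    tpm <- computeTPM(matrix(c(100, 100), 2, 1), lengths = c(1000, 2000))
    expect_equal(tpm[, 1], c(2e6 / 3, 1e6 / 3), tolerance = 1e-8)
    # column sums on simulated data
    cfg <- quickConfig(seed = 71)
    se <- computeTPM(generateCounts(generateAnnotation(cfg), cfg)$se)
    expect_equal(unname(colSums(assay(se, "tpm"))), rep(1e6, 11),
                 tolerance = 1e-6)
    # all-zero sample flagged, not an error
    m <- matrix(c(5, 3, 0, 0), 2, 2)
    expect_warning(z <- computeTPM(m, lengths = c(100, 100)), "all-zero")
    expect_equal(z[, 2], c(0, 0))
    expect_error(computeTPM(m, lengths = c(0, 100)), "> 0")
})

test_that("differential expression is null on identical groups and honors
           strict thresholds", {
    counts <- matrix(rep(c(100, 40, 250, 7, 90), each = 8), 5, 8,
                     byrow = TRUE,
                     dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
    se <- SexExperiment(counts, lengths = rep(1000, 5),
                        sex = rep(c("female", "male"), each = 4))
    res <- differentialExpression(se)
    expect_equal(res$log2_fold_change, rep(0, 5), tolerance = 1e-10)
    expect_false(any(res$is_deg))
    # a gene at exactly FC = 1.5 is never a DEG (strict >)
    counts2 <- counts
    counts2["g1", ] <- rep(c(100, 150), each = 4)
    se2 <- SexExperiment(counts2, lengths = rep(1000, 5),
                         sex = rep(c("female", "male"), each = 4))
    res2 <- differentialExpression(se2)
    expect_equal(res2$log2_fold_change[res2$gene_id == "g1"], log2(1.5),
                 tolerance = 1e-6)
    expect_false(res2$is_deg[res2$gene_id == "g1"])
    # all-zero genes are excluded and reported
    counts3 <- rbind(counts, gz = 0)
    se3 <- SexExperiment(counts3, lengths = rep(1000, 6),
                         sex = rep(c("female", "male"), each = 4))
    res3 <- differentialExpression(se3)
    expect_equal(attr(res3, "excluded"), "gz")
    expect_false("gz" %in% res3$gene_id)
    expect_error(differentialExpression(
        SexExperiment(counts[, 1:3], lengths = rep(1000, 5),
                      sex = c("female", "male", "male"))),
        "two samples per sex")
})

test_that("swapping sex labels negates every log2 fold change", {
    cfg <- quickConfig(seed = 81)
    out <- generateCounts(generateAnnotation(cfg), cfg)
    sex <- sampleSex(out$se)
    flipped <- ifelse(sex == "male", "female", "male")
    seF <- SexExperiment(assay(out$se, "counts"),
                         lengths = featureLengths(out$se), sex = flipped)
    a <- differentialExpression(out$se)
    b <- differentialExpression(seF)
    expect_equal(a$log2_fold_change, -b$log2_fold_change, tolerance = 1e-6)
})

test_that("the NB-GLM stand-in tracks an established DE framework", {
    cfg <- quickConfig(seed = 91)
    out <- generateCounts(generateAnnotation(cfg), cfg)
    res <- differentialExpression(out$se)
    dds <- DESeq2::DESeqDataSetFromMatrix(
        assay(out$se, "counts")[res$gene_id, ],
        data.frame(sex = factor(sampleSex(out$se),
                                levels = c("female", "male"))),
        design = ~sex)
    dres <- DESeq2::results(suppressMessages(DESeq2::DESeq(dds, quiet = TRUE)))
    keep <- !is.na(dres$log2FoldChange) & !is.na(res$log2_fold_change)
    expect_gt(cor(res$log2_fold_change[keep], dres$log2FoldChange[keep]),
              0.95)
    # the spiked truth genes agree in sign between the two routes
    tru <- out$truth$deg
    i <- match(tru$gene_id, res$gene_id)
    expect_true(all(sign(res$log2_fold_change[i]) ==
                    sign(tru$log2fc_male_vs_female)))
})

test_that("group enrichment equals exhaustive hypergeometric enumeration", {
    # spec'd worked table: 8/10 DEGs in group vs 20/90 non-DEGs in group
    deg <- paste0("d", 1:10)
    bg <- c(deg, paste0("n", 1:90))
    grp <- c(deg[1:8], paste0("n", 1:20))
    res <- groupEnrichment(deg, list(G = grp), bg)
    expect_equal(res$p, enumFisherP(8, 2, 20, 70), tolerance = 1e-12)
    expect_equal(res$direction, "over")
    expect_true(res$significant)
    # DEG set = background -> degenerate table, p = 1
    resAll <- groupEnrichment(bg, list(G = grp), bg)
    expect_equal(resAll$p, 1)
    # group absent from the DEG set but common in background -> under
    resU <- groupEnrichment(deg, list(G = paste0("n", 1:60)), bg)
    expect_equal(resU$direction, "under")
    # random tables with total <= 60 match the enumeration oracle
    set.seed(7)
    for (rep in 1:40) {
        tot <- sample(8:60, 1)
        a <- sample(0:tot, 1); b <- sample(0:(tot - a), 1)
        c_ <- sample(0:(tot - a - b), 1); d <- tot - a - b - c_
        if (a + b == 0 || c_ + d == 0 || a + c_ == 0 || b + d == 0) next
        degIds <- sprintf("x%03d", seq_len(a + b))
        bgIds <- sprintf("x%03d", seq_len(tot))
        grpIds <- c(degIds[seq_len(a)],
                    setdiff(bgIds, degIds)[seq_len(c_)])
        r <- groupEnrichment(degIds, list(G = grpIds), bgIds)
        expect_equal(r$p, enumFisherP(a, b, c_, d), tolerance = 1e-9)
    }
    expect_warning(groupEnrichment(deg, list(E = "zzz"), bg), "skipped")
    expect_error(groupEnrichment("absent", list(G = grp), bg), "subset")
})

test_that("ddCt fold changes follow the 2^-ddCt arithmetic", {
    expect_equal(ddctFoldChange(20, c(19, 21), 20, c(19, 21)), 1)
    expect_equal(ddctFoldChange(19, c(19, 21), 20, c(19, 21)), 2)
    # refs (20, 22): dCt_case = 21 - 21 = 0; control dCt 0 -> fold 1
    expect_equal(ddctFoldChange(21, c(20, 22), 21, c(20, 22)), 1)
    # one cycle below the reference mean in the case only -> fold 2
    expect_equal(ddctFoldChange(20, c(20, 22), 21, c(20, 22)), 2)
    expect_error(ddctFoldChange(NA, 20, 20, 20))
})
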