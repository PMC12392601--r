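#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generators. Defaults
#' encode the study conditions the pipeline is meant to exercise: an 11-
#' sample RNA-seq design (6 female, 5 male pooled replicates), a five-stratum
#' blastocyst cohort (Day 7 expanded/hatched, Day 8 non-expanded/expanded/
#' hatched) with male-biased developmental progression, modest X dosage
#' upregulation in females, negative-binomial counts, and junction counts
#' with group-specific PSI. All draws flow from one root seed through named
#' substreams, so each generator is reproducible on its own.
#'
#' @param seed integer root seed.
#' @param nAutosomes number of autosomes in the toy genome.
#' @param genesPerChrom genes per autosome (X gets the same; Y one fifth).
#' @param nFemale,nMale RNA-seq replicates per sex.
#' @param xDosageFactorFemale,xDosageFactorMale multiplier on X-linked
#'   expression per sex (female 1.3: partial compensatory upregulation).
#' @param fracAutosomalDeg fraction of autosomal coding genes spiked as DEGs.
#' @param degLog2fc spiked |log2 fold change| (sign random per gene).
#' @param nbDispersion NB dispersion (1/size).
#' @param depth expected library size (reads/sample).
#' @param cohortDesign data.frame(day, stage, n, male_frac): embryos
#'   collected per stratum and the male fraction among developed embryos;
#'   defaults reproduce the observed stage-wise male bias of a 444-embryo
#'   IVF cohort.
#' @param maleStageAdvantage scaling of the per-stratum male log-odds
#'   (1 = as designed, 0 = no sex difference).
#' @param sexingFailureRate probability an embryo yields no autosomal
#'   amplicon (default 32/444).
#' @param yLeakRate expected relative leakage of Y-gene counts into females
#'   (and of the XIST-like gene into males); 0 = none.
#' @param fracParalog,fracTf,fracTfCofactor,fracEscapee annotation flag
#'   fractions.
#' @param nSeEvents number of skipped-exon events.
#' @param fracDifferentialSe fraction of SE events with a sex-specific PSI.
#' @param deltaPsi PSI difference for differential events.
#' @param junctionDepth expected junction reads per event and sample.
#' @param psiTable optional data.frame(psi_female, psi_male) overriding the
#'   event PSI design.
#' @param fracBiasedIsoforms,isoformLog2fc sex-biased isoform spiking.
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nAutosomes = 5L,
                             genesPerChrom = 40L,
                             nFemale = 6L, nMale = 5L,
                             xDosageFactorFemale = 1.3,
                             xDosageFactorMale = 1.0,
                             fracAutosomalDeg = 0.1,
                             degLog2fc = 2,
                             nbDispersion = 0.05,
                             depth = 1e6,
                             cohortDesign = NULL,
                             maleStageAdvantage = 1,
                             sexingFailureRate = 32 / 444,
                             yLeakRate = 0,
                             fracParalog = 0.2,
                             fracTf = 0.1,
                             fracTfCofactor = 0.05,
                             fracEscapee = 0.15,
                             nSeEvents = 60L,
                             fracDifferentialSe = 0.15,
                             deltaPsi = 0.3,
                             junctionDepth = 200,
                             psiTable = NULL,
                             fracBiasedIsoforms = 0.1,
                             isoformLog2fc = 2) {
    if (is.null(cohortDesign))
        cohortDesign <- data.frame(
            day = c(7L, 7L, 8L, 8L, 8L),
            stage = c("expanded", "hatched", "non_expanded", "expanded",
                      "hatched"),
            n = c(167L, 13L, 107L, 120L, 37L),
            male_frac = c(107 / 155, 8 / 12, 80 / 99, 91 / 112, 29 / 34))
    cfg <- list(seed = as.integer(seed), nAutosomes = as.integer(nAutosomes),
                genesPerChrom = as.integer(genesPerChrom),
                nFemale = as.integer(nFemale), nMale = as.integer(nMale),
                xDosageFactorFemale = xDosageFactorFemale,
                xDosageFactorMale = xDosageFactorMale,
                fracAutosomalDeg = fracAutosomalDeg, degLog2fc = degLog2fc,
                nbDispersion = nbDispersion, depth = depth,
                cohortDesign = cohortDesign,
                maleStageAdvantage = maleStageAdvantage,
                sexingFailureRate = sexingFailureRate,
                yLeakRate = yLeakRate,
                fracParalog = fracParalog, fracTf = fracTf,
                fracTfCofactor = fracTfCofactor, fracEscapee = fracEscapee,
                nSeEvents = as.integer(nSeEvents),
                fracDifferentialSe = fracDifferentialSe,
                deltaPsi = deltaPsi, junctionDepth = junctionDepth,
                psiTable = psiTable,
                fracBiasedIsoforms = fracBiasedIsoforms,
                isoformLog2fc = isoformLog2fc)
    .checkFraction(c(cfg$fracAutosomalDeg, cfg$sexingFailureRate,
                     cfg$yLeakRate, cfg$fracParalog, cfg$fracTf,
                     cfg$fracTfCofactor, cfg$fracEscapee,
                     cfg$fracDifferentialSe, cfg$fracBiasedIsoforms,
                     cfg$cohortDesign$male_frac),
                   "config fractions")
    if (!is.null(psiTable))
        .checkFraction(c(psiTable$psi_female, psiTable$psi_male),
                       "PSI values")
    stopifnot(cfg$depth > 0, cfg$junctionDepth > 0, cfg$nbDispersion > 0,
              cfg$xDosageFactorFemale > 0, cfg$xDosageFactorMale > 0,
              all(cfg$cohortDesign$n > 0))
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a sexed blastocyst cohort
#'
#' Embryos are drawn per day/stage stratum; within each stratum the
#' probability of being male is \code{plogis(adv * qlogis(male_frac))} with
#' \code{adv = maleStageAdvantage}, so males reach later stages with higher
#' probability when \code{adv > 0} and the sex ratio is 1 at every stage
#' when \code{adv = 0}. PCR amplicons derive from the true sex; a sexing
#' failure (probability \code{sexingFailureRate}) leaves both amplicons
#' absent, and \code{\link{callSexFromAmplicons}} supplies the called sex.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return data.frame: \code{embryo_id}, \code{day}, \code{stage},
#'   \code{true_sex}, \code{autosomal_amplicon}, \code{y_amplicon},
#'   \code{called_sex}.
#' @export
generateCohort <- function(config) {
    des <- config$cohortDesign
    if (sum(des$n) <= 0) stop("cohort size must be positive")
    .withSubstream(config$seed, "cohort", {
        rows <- lapply(seq_len(nrow(des)), function(i) {
            n <- des$n[i]
            pMale <- stats::plogis(config$maleStageAdvantage *
                                   stats::qlogis(des$male_frac[i]))
            male <- stats::rbinom(n, 1, pMale) == 1
            fail <- stats::runif(n) < config$sexingFailureRate
            data.frame(day = des$day[i], stage = des$stage[i],
                       true_sex = ifelse(male, "male", "female"),
                       autosomal_amplicon = ifelse(fail, "absent", "present"),
                       y_amplicon = ifelse(!fail & male, "present", "absent"))
        })
        out <- do.call(rbind, rows)
        out$embryo_id <- sprintf("embryo_%03d", seq_len(nrow(out)))
        out$called_sex <- callSexFromAmplicons(out$autosomal_amplicon,
                                               out$y_amplicon)
        out[, c("embryo_id", "day", "stage", "true_sex",
                "autosomal_amplicon", "y_amplicon", "called_sex")]
    })
}

.BASES <- c("A", "C", "G", "T")
.STOPS <- c("TAA", "TAG", "TGA")
.CODONS61 <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1,
                           paste, collapse = ""), .STOPS)

# spliced positions (transcription order) of a transcript's exons
.splicedPositions <- function(exons, strand) {
    exons <- exons[order(start(exons))]
    pos <- unlist(lapply(seq_along(exons), function(i)
        seq(start(exons)[i], end(exons)[i])))
    if (strand == "-") rev(pos) else pos
}

#' Simulate a toy genome annotation (and sequences)
#'
#' Builds chromosomes \code{autosome_1..N}, \code{X} and \code{Y}, each with
#' spaced multi-exon genes on both strands. Every protein-coding gene has
#' one transcript with an in-frame CDS (ATG ... stop, length divisible by 3,
#' no internal stop) placed inside its exons with short UTRs; one X-linked
#' non-coding gene (\code{XIST_like}) is expressed from the inactive X in
#' females only. Gene flags (TF, TF cofactor, paralog, XCI escapee) are
#' sampled at the configured fractions. Chromosome sequences are random DNA
#' with the designed CDS codons written in, so CDS translation is exact.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{annotation} (a \linkS4class{TxAnnotation}) and
#'   \code{genome} (a named \code{DNAStringSet}).
#' @export
generateAnnotation <- function(config) {
    .withSubstream(config$seed, "annotation", {
        chroms <- c(paste0("autosome_", seq_len(config$nAutosomes)), "X", "Y")
        nGenes <- c(rep(config$genesPerChrom, config$nAutosomes),
                    config$genesPerChrom,
                    max(3L, config$genesPerChrom %/% 5L))
        geneRows <- list()
        exChrom <- exStrand <- exTx <- character()
        exStart <- exEnd <- integer()
        cdChrom <- cdStrand <- cdTx <- character()
        cdStart <- cdEnd <- integer()
        txGene <- character()
        for (ci in seq_along(chroms)) {
            chrom <- chroms[ci]
            cursor <- 2001L
            for (gi in seq_len(nGenes[ci])) {
                gid <- sprintf("%s_g%03d", chrom, gi)
                tid <- paste0(gid, "_t1")
                nEx <- sample(3:8, 1)
                exLen <- sample(100:300, nEx, replace = TRUE)
                inLen <- sample(200:800, max(nEx - 1, 0), replace = TRUE)
                en <- cursor + cumsum(exLen) + c(0L, cumsum(inLen)) - 1L
                st <- en - exLen + 1L
                strand <- sample(c("+", "-"), 1)
                isXist <- chrom == "X" && gi == 1L
                totLen <- sum(exLen)
                geneRows[[gid]] <- data.frame(
                    gene_id = gid, chrom = chrom, strand = strand,
                    start = st[1], end = en[nEx],
                    chrom_class = if (ci <= config$nAutosomes) "autosome"
                                  else chrom,
                    biotype = if (isXist) "lncRNA" else "protein_coding",
                    tx_id = tid, tx_len = totLen)
                exChrom <- c(exChrom, rep(chrom, nEx))
                exStrand <- c(exStrand, rep(strand, nEx))
                exTx <- c(exTx, rep(tid, nEx))
                exStart <- c(exStart, st); exEnd <- c(exEnd, en)
                txGene[tid] <- gid
                if (!isXist) {
                    # CDS = spliced interval [utr5+1, utr5+cdsLen] mapped
                    # through the exons; for minus-strand genes the 5' UTR
                    # sits at the high-coordinate end
                    utr5 <- 30L
                    cdsLen <- 3L * ((totLen - 60L) %/% 3L)
                    if (strand == "+") { lo <- utr5 + 1L
                                         hi <- utr5 + cdsLen }
                    else { lo <- totLen - (utr5 + cdsLen) + 1L
                           hi <- totLen - utr5 }
                    cw <- cumsum(exLen)
                    sOff <- c(0L, cw[-nEx])   # spliced offset before exon
                    for (e in seq_len(nEx)) {
                        a <- max(lo, sOff[e] + 1L)
                        b <- min(hi, cw[e])
                        if (a > b) next
                        cdChrom <- c(cdChrom, chrom)
                        cdStrand <- c(cdStrand, strand)
                        cdTx <- c(cdTx, tid)
                        cdStart <- c(cdStart, st[e] + (a - sOff[e] - 1L))
                        cdEnd <- c(cdEnd, st[e] + (b - sOff[e] - 1L))
                    }
                }
                cursor <- en[nEx] + 2000L
            }
        }
        exonList <- S4Vectors::split(
            GRanges(exChrom, IRanges(exStart, exEnd), strand = exStrand),
            factor(exTx, levels = unique(exTx)))
        cdsList <- S4Vectors::split(
            GRanges(cdChrom, IRanges(cdStart, cdEnd), strand = cdStrand),
            factor(cdTx, levels = unique(cdTx)))
        genes <- do.call(rbind, geneRows)
        rownames(genes) <- NULL
        nG <- nrow(genes)
        genes$is_paralog <- stats::runif(nG) < config$fracParalog
        genes$is_tf <- stats::runif(nG) < config$fracTf
        genes$is_tf_cofactor <- !genes$is_tf &
            stats::runif(nG) < config$fracTfCofactor
        genes$is_escapee <- genes$chrom_class == "X" &
            stats::runif(nG) < config$fracEscapee
        genes$is_xist_like <- genes$biotype == "lncRNA" &
            genes$chrom_class == "X"

        ann <- TxAnnotation(genes, exonList, cdsList, txGene)

        genome <- .withSubstream(config$seed, "sequences",
                                 .buildGenome(ann, chroms))
        list(annotation = ann, genome = genome)
    })
}

.buildGenome <- function(annotation, chroms) {
    genes <- geneInfo(annotation)
    lens <- vapply(chroms, function(ch) {
        g <- genes[genes$chrom == ch, ]
        max(g$end) + 2000L
    }, 0L)
    seqs <- lapply(lens, function(L)
        sample(.BASES, L, replace = TRUE))
    names(seqs) <- chroms
    # flatten CDS once; GRangesList element extraction is too slow per-tx
    ucds <- unlist(cdsBy(annotation), use.names = TRUE)
    df <- data.frame(tx = names(ucds),
                     chrom = as.character(seqnames(ucds)),
                     strand = as.character(strand(ucds)),
                     start = start(ucds), end = end(ucds))
    for (grp in split(df, df$tx)) {
        grp <- grp[order(grp$start), ]
        L <- sum(grp$end - grp$start + 1L)
        coding <- c("ATG",
                    sample(.CODONS61, L / 3 - 2, replace = TRUE), "TAA")
        nt <- strsplit(paste(coding, collapse = ""), "")[[1]]
        pos <- unlist(mapply(seq, grp$start, grp$end, SIMPLIFY = FALSE))
        if (grp$strand[1] == "-") {
            pos <- rev(pos)
            nt <- chartr("ACGT", "TGCA", nt)
        }
        seqs[[grp$chrom[1]]][pos] <- nt
    }
    DNAStringSet(vapply(seqs, paste, "", collapse = ""))
}

#' Simulate a gene-level count matrix with known sex effects
#'
#' Negative-binomial counts for all annotated genes over an
#' \code{nFemale + nMale} replicate design. Gene means are
#' \code{libsize x relative abundance x sex factor}: Y-linked genes are
#' (near) zero in females and the XIST-like gene (near) zero in males
#' (\code{yLeakRate} controls the leakage), X-linked genes are scaled by the
#' sex-specific dosage factor, and a random \code{fracAutosomalDeg} of
#' autosomal coding genes get a signed \code{degLog2fc} shift. Library
#' sizes vary log-normally around \code{depth}.
#'
#' @param annotationSet output of \code{\link{generateAnnotation}} (or a
#'   \linkS4class{TxAnnotation}).
#' @param config a \code{\link{simulationConfig}}.
#' @param sex optional explicit sample sex vector; defaults to
#'   \code{nFemale} females then \code{nMale} males.
#' @return list: \code{se} (a \linkS4class{SexExperiment} with gene metadata
#'   in rowData) and \code{truth} (per-sample sex, the DEG table with signed
#'   effects, dosage factors).
#' @export
generateCounts <- function(annotationSet, config, sex = NULL) {
    ann <- if (is(annotationSet, "TxAnnotation")) annotationSet
           else annotationSet$annotation
    genes <- geneInfo(ann)
    if (nrow(genes) == 0) stop("empty annotation")
    if (is.null(sex))
        sex <- c(rep("female", config$nFemale), rep("male", config$nMale))
    .withSubstream(config$seed, "counts", {
        nG <- nrow(genes); nS <- length(sex)
        rel <- stats::rgamma(nG, shape = 0.7, rate = 1)
        rel[genes$is_xist_like] <- stats::quantile(rel, 0.95)
        rel <- rel / sum(rel)
        autoCoding <- which(genes$chrom_class == "autosome" &
                            genes$biotype == "protein_coding")
        nDeg <- round(config$fracAutosomalDeg * length(autoCoding))
        degIdx <- sample(autoCoding, nDeg)
        degSign <- sample(c(-1, 1), nDeg, replace = TRUE)
        libsize <- config$depth * exp(stats::rnorm(nS, 0, 0.1))
        fac <- matrix(1, nG, nS)
        isX <- genes$chrom_class == "X" & !genes$is_xist_like
        isY <- genes$chrom_class == "Y"
        for (s in seq_len(nS)) {
            female <- sex[s] == "female"
            fac[isX, s] <- if (female) config$xDosageFactorFemale
                           else config$xDosageFactorMale
            fac[isY, s] <- if (female) config$yLeakRate else 1
            fac[genes$is_xist_like, s] <-
                if (female) 1 else config$yLeakRate
            if (!female && nDeg > 0)
                fac[degIdx, s] <- fac[degIdx, s] * 2^(degSign *
                                                      config$degLog2fc)
        }
        mu <- outer(rel, libsize) * fac
        counts <- matrix(stats::rnbinom(nG * nS, mu = mu,
                                        size = 1 / config$nbDispersion),
                         nG, nS)
        dimnames(counts) <- list(genes$gene_id,
                                 sprintf("%s_%02d", sex, seq_len(nS)))
        se <- SexExperiment(counts, lengths = genes$tx_len, sex = sex,
                            rowData = genes)
        truth <- list(
            sex = stats::setNames(sex, colnames(counts)),
            deg = data.frame(gene_id = genes$gene_id[degIdx],
                             log2fc_male_vs_female = degSign *
                                 config$degLog2fc),
            x_dosage = c(female = config$xDosageFactorFemale,
                         male = config$xDosageFactorMale))
        list(se = se, truth = truth)
    })
}

#' Simulate skipped-exon events with group-specific PSI
#'
#' Each event is anchored to a real internal exon of a generated transcript.
#' Per event and sample, total junction reads are Poisson with mean
#' \code{junctionDepth} and inclusion reads are binomial with success
#' probability \eqn{\psi l_I / (\psi l_I + (1-\psi) l_S)} (\eqn{l_I = 2},
#' \eqn{l_S = 1}) -- the same effective-length weighting the PSI estimator
#' inverts, so estimator consistency is testable. The event PSI design comes
#' from \code{config$psiTable} or is drawn: a fraction
#' \code{fracDifferentialSe} of events get \code{deltaPsi} between sexes.
#'
#' @param annotationSet output of \code{\link{generateAnnotation}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param sex optional sample sex vector (defaults as in
#'   \code{\link{generateCounts}}).
#' @return list: \code{events} (an \linkS4class{SEEventSet}) and
#'   \code{truth} (per-event generating PSI per sex and a differential flag).
#' @export
generateSeEvents <- function(annotationSet, config, sex = NULL) {
    ann <- if (is(annotationSet, "TxAnnotation")) annotationSet
           else annotationSet$annotation
    if (is.null(sex))
        sex <- c(rep("female", config$nFemale), rep("male", config$nMale))
    ex <- exonsBy(ann)
    candidates <- names(ex)[vapply(ex, length, 0L) >= 3]
    .withSubstream(config$seed, "se_events", {
        psiTab <- config$psiTable
        if (is.null(psiTab)) {
            n <- config$nSeEvents
            base <- stats::runif(n, 0.15, 0.85)
            diffEv <- stats::runif(n) < config$fracDifferentialSe
            shift <- ifelse(stats::runif(n) < 0.5, 1, -1) * config$deltaPsi
            psiM <- ifelse(diffEv, pmin(pmax(base + shift / 2, 0.02), 0.98),
                           base)
            psiF <- ifelse(diffEv, pmin(pmax(base - shift / 2, 0.02), 0.98),
                           base)
            psiTab <- data.frame(psi_female = psiF, psi_male = psiM)
        }
        .checkFraction(c(psiTab$psi_female, psiTab$psi_male), "PSI values")
        n <- nrow(psiTab)
        txPick <- sample(candidates, n, replace = n > length(candidates))
        # exon coordinate cache keeps the per-event loop off the S4 path
        uniqTx <- unique(txPick)
        cache <- lapply(ex[uniqTx], function(e) {
            o <- order(start(e))
            list(st = start(e)[o], en = end(e)[o],
                 chrom = as.character(seqnames(e))[1],
                 strand = as.character(strand(e))[1])
        })
        exS <- exE <- upE <- dnS <- integer(n)
        chr <- strd <- character(n)
        for (i in seq_len(n)) {
            c_ <- cache[[txPick[i]]]
            internal <- seq(2, length(c_$st) - 1)
            j <- internal[sample.int(length(internal), 1)]
            exS[i] <- c_$st[j]; exE[i] <- c_$en[j]
            upE[i] <- c_$en[j - 1]; dnS[i] <- c_$st[j + 1]
            chr[i] <- c_$chrom; strd[i] <- c_$strand
        }
        events <- data.frame(event_id = sprintf("SE_%04d", seq_len(n)),
                             gene_id = unname(txToGene(ann)[txPick]),
                             transcript_id = txPick,
                             chrom = chr, strand = strd,
                             exon_start = exS, exon_end = exE,
                             upstream_end = upE, downstream_start = dnS,
                             inc_len = 2, skip_len = 1)
        nS <- length(sex)
        I <- matrix(0L, n, nS); S <- matrix(0L, n, nS)
        for (s in seq_len(nS)) {
            psi <- if (sex[s] == "female") psiTab$psi_female
                   else psiTab$psi_male
            tot <- stats::rpois(n, config$junctionDepth)
            pInc <- psi * events$inc_len /
                (psi * events$inc_len + (1 - psi) * events$skip_len)
            I[, s] <- stats::rbinom(n, tot, pInc)
            S[, s] <- tot - I[, s]
        }
        colnames(I) <- colnames(S) <- sprintf("%s_%02d", sex, seq_len(nS))
        truth <- data.frame(event_id = events$event_id,
                            psi_female = psiTab$psi_female,
                            psi_male = psiTab$psi_male,
                            differential = psiTab$psi_female !=
                                psiTab$psi_male)
        list(events = SEEventSet(events, I, S, sex), truth = truth)
    })
}

#' Simulate PFAM-style domain hits with controlled filter outcomes
#'
#' Emits hits on coding transcripts: a block of clean passes, one hit
#' failing exactly one of the five confidence criteria for each criterion
#' (at the threshold boundary where the semantics bite), hits whose
#' amino-acid span crosses an exon junction, and -- when skipped-exon events
#' are supplied -- hits placed inside a skipped exon (disrupted) and in
#' exons untouched by any event (intact). Ground-truth disruption labels are
#' fixed by construction.
#'
#' @param annotationSet output of \code{\link{generateAnnotation}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seEvents optional \linkS4class{SEEventSet} whose skipped exons the
#'   disrupted hits target.
#' @return list: \code{hits} (data.frame in domtblout-like columns) and
#'   \code{truth} (hit id, expected filter pass, expected disruption).
#' @export
generateDomainHits <- function(annotationSet, config, seEvents = NULL) {
    ann <- if (is(annotationSet, "TxAnnotation")) annotationSet
           else annotationSet$annotation
    .withSubstream(config$seed, "domain_hits", {
        pass <- list(domain_score = 50, domain_evalue = 1e-6,
                     seq_evalue = 1e-10, accuracy = 0.95, coverage = 0.97)
        fails <- list(domain_score = 10, domain_evalue = 0.02,
                      seq_evalue = 1e-4, accuracy = 0.7, coverage = 0.8)
        txs <- names(cdsBy(ann))
        hits <- list(); truth <- list()
        addHit <- function(tx, aaS, aaE, metrics, passes, disrupted) {
            id <- sprintf("hit_%03d", length(hits) + 1L)
            hits[[length(hits) + 1L]] <<- data.frame(
                hit_id = id, protein_id = tx,
                domain_name = sprintf("PF%05d_like", length(hits) + 1L),
                aa_start = aaS, aa_end = aaE,
                domain_score = metrics$domain_score,
                domain_evalue = metrics$domain_evalue,
                seq_evalue = metrics$seq_evalue,
                accuracy = metrics$accuracy, coverage = metrics$coverage)
            truth[[length(truth) + 1L]] <<- data.frame(
                hit_id = id, passes_filter = passes, disrupted = disrupted)
        }
        protLen <- function(tx) sum(width(cdsBy(ann)[[tx]])) %/% 3L - 1L
        aaInExon <- function(tx, lo, hi) {
            # codons whose three bases all fall inside [lo, hi]
            pos <- .cdsPositionMap(ann, tx)
            nAA <- protLen(tx)
            ok <- vapply(seq_len(nAA), function(k) {
                p <- pos[(3 * k - 2):(3 * k)]
                all(p >= lo & p <= hi)
            }, TRUE)
            which(ok)
        }
        # clean passes + one single-criterion failure per criterion
        for (m in names(fails)) {
            bad <- pass; bad[[m]] <- fails[[m]]
            tx <- sample(txs, 1)
            n <- protLen(tx)
            addHit(tx, 2, min(n, 20), bad, passes = FALSE, disrupted = NA)
        }
        # junction-straddling passing hits
        multi <- txs[vapply(txs, function(t)
            length(cdsBy(ann)[[t]]) >= 2, TRUE)]
        for (tx in sample(multi, min(3, length(multi)))) {
            w <- cumsum(width(cdsBy(ann)[[tx]]))
            aaJ <- ceiling(w[1] / 3)  # codon at/after the first junction
            n <- protLen(tx)
            aaS <- max(1, aaJ - 3); aaE <- min(n, aaJ + 3)
            addHit(tx, aaS, aaE, pass, passes = TRUE, disrupted = NA)
        }
        if (!is.null(seEvents)) {
            ev <- eventInfo(seEvents)
            used <- 0
            for (i in seq_len(nrow(ev))) {
                if (used >= 4) break
                tx <- ev$transcript_id[i]
                if (is.null(cdsBy(ann)[[tx]])) next
                inside <- aaInExon(tx, ev$exon_start[i], ev$exon_end[i])
                if (length(inside) < 3) next
                addHit(tx, min(inside), min(inside) + 2, pass,
                       passes = TRUE, disrupted = TRUE)
                used <- used + 1
            }
            # intact hits: transcripts carrying no event at all
            quiet <- setdiff(txs, ev$transcript_id)
            for (tx in sample(quiet, min(4, length(quiet)))) {
                n <- protLen(tx)
                addHit(tx, 2, min(n, 10), pass, passes = TRUE,
                       disrupted = FALSE)
            }
        }
        list(hits = do.call(rbind, hits), truth = do.call(rbind, truth))
    })
}

#' Simulate long-read isoform chains of every category
#'
#' Derives chains from the reference annotation so each SQANTI-style
#' category is represented with a known label: exact reference chains (FSM),
#' consecutive sub-chains (ISM), exon-skipping recombinations of known
#' splice sites (NIC), chains with a shifted (novel) splice site (NNC),
#' mono-exonic chains in gene deserts (intergenic), on the opposite strand
#' of a gene (antisense), inside an intron (genic_genomic), and chains
#' bridging two adjacent same-strand genes (fusion). Per-sample isoform
#' counts are NB-distributed with a fraction of isoforms spiked with a sex
#' effect.
#'
#' @param annotationSet output of \code{\link{generateAnnotation}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param nPerCategory chains per category (default 3 where possible).
#' @param sex optional sample sex vector for the count matrix.
#' @return list: \code{chains} (data.frame with list-columns
#'   \code{intron_starts}/\code{intron_ends}), \code{truth} (isoform id,
#'   true category, source transcript), \code{counts} (a
#'   \linkS4class{SexExperiment}) and \code{truthCounts} (spiked isoforms
#'   with signed effects).
#' @export
generateIsoformChains <- function(annotationSet, config, nPerCategory = 3,
                                  sex = NULL) {
    ann <- if (is(annotationSet, "TxAnnotation")) annotationSet
           else annotationSet$annotation
    if (is.null(sex))
        sex <- c(rep("female", config$nFemale), rep("male", config$nMale))
    ex <- exonsBy(ann)
    genes <- geneInfo(ann)
    idx <- .referenceIndex(ann)
    multi <- names(ex)[vapply(ex, length, 0L) >= 3]
    .withSubstream(config$seed, "isoform_chains", {
        rows <- list(); truth <- list()
        add <- function(chrom, strand, startP, endP, istarts, iends,
                        category, src) {
            id <- sprintf("iso_%03d", length(rows) + 1L)
            df <- data.frame(isoform_id = id, chrom = chrom,
                             strand = strand, start = startP, end = endP)
            df$intron_starts <- list(as.integer(istarts))
            df$intron_ends <- list(as.integer(iends))
            rows[[length(rows) + 1L]] <<- df
            truth[[length(truth) + 1L]] <<- data.frame(
                isoform_id = id, true_category = category,
                source_transcript = src)
        }
        chainOf <- function(tx) idx$chains[[tx]]
        meta <- function(tx) {
            e <- ex[[tx]]
            list(chrom = as.character(seqnames(e))[1],
                 strand = as.character(strand(e))[1],
                 start = min(start(e)), end = max(end(e)))
        }
        picks <- sample(multi, min(4 * nPerCategory, length(multi)))
        grp <- split(picks, rep(1:4, length.out = length(picks)))
        for (tx in grp[[1]]) {   # FSM
            m <- meta(tx); c_ <- chainOf(tx)
            add(m$chrom, m$strand, m$start, m$end, c_$starts, c_$ends,
                "FSM", tx)
        }
        for (tx in grp[[2]]) {   # ISM: drop the first intron, start inside
            m <- meta(tx); c_ <- chainOf(tx)
            add(m$chrom, m$strand, c_$ends[1] + 5L, m$end,
                c_$starts[-1], c_$ends[-1], "ISM", tx)
        }
        for (tx in grp[[3]]) {   # NIC: skip an internal exon
            m <- meta(tx); c_ <- chainOf(tx)
            k <- length(c_$starts)
            j <- sample(seq_len(k - 1), 1)
            ns <- c_$starts[-(j + 1)]
            ne <- c_$ends[-j]
            add(m$chrom, m$strand, m$start, m$end, ns, ne, "NIC", tx)
        }
        for (tx in grp[[4]]) {   # NNC: novel acceptor 9 bp downstream
            m <- meta(tx); c_ <- chainOf(tx)
            ne <- c_$ends; ne[1] <- ne[1] + 9L
            add(m$chrom, m$strand, m$start, m$end, c_$starts, ne, "NNC", tx)
        }
        # gene-overlap categories
        ord <- genes[order(genes$chrom, genes$start), ]
        gapG <- ord[1, ]         # intergenic: before the first gene
        add(gapG$chrom, "+", 100L, 500L, integer(), integer(),
            "intergenic", NA)
        anti <- genes[sample(nrow(genes), 1), ]
        add(anti$chrom, if (anti$strand == "+") "-" else "+",
            anti$start + 10L, anti$start + 400L, integer(), integer(),
            "antisense", NA)
        donor <- NULL            # genic_genomic: mono-exonic inside intron 1
        for (tx in multi) {
            c_ <- chainOf(tx)
            if (c_$ends[1] - c_$starts[1] > 120) { donor <- tx; break }
        }
        if (!is.null(donor)) {
            m <- meta(donor); c_ <- chainOf(donor)
            add(m$chrom, m$strand, c_$starts[1] + 10L, c_$starts[1] + 100L,
                integer(), integer(), "genic_genomic", donor)
        }
        fusionDone <- FALSE      # fusion: bridge two same-strand neighbours
        for (i in seq_len(nrow(ord) - 1)) {
            g1 <- ord[i, ]; g2 <- ord[i + 1, ]
            if (g1$chrom == g2$chrom && g1$strand == g2$strand &&
                g1$end < g2$start && !fusionDone) {
                t1 <- g1$tx_id; t2 <- g2$tx_id
                c1 <- chainOf(t1); c2 <- chainOf(t2)
                if (is.null(c1) || is.null(c2)) next
                add(g1$chrom, g1$strand, g1$start, g2$end,
                    c(c1$starts, g1$end + 1L, c2$starts),
                    c(c1$ends, g2$start - 1L, c2$ends), "fusion",
                    paste(t1, t2, sep = "+"))
                fusionDone <- TRUE
            }
        }
        chains <- do.call(rbind, rows)
        truth <- do.call(rbind, truth)

        # per-sample isoform counts with optional sex bias
        nI <- nrow(chains); nS <- length(sex)
        rel <- stats::rgamma(nI, 0.9, 1); rel <- rel / sum(rel)
        nBias <- round(config$fracBiasedIsoforms * nI)
        biasIdx <- sample(nI, nBias)
        biasSign <- sample(c(-1, 1), nBias, replace = TRUE)
        mu <- outer(rel, rep(config$depth / 100, nS))
        for (s in which(sex == "male"))
            mu[biasIdx, s] <- mu[biasIdx, s] * 2^(biasSign *
                                                  config$isoformLog2fc)
        counts <- matrix(stats::rnbinom(nI * nS, mu = mu,
                                        size = 1 / config$nbDispersion),
                         nI, nS,
                         dimnames = list(chains$isoform_id,
                                         sprintf("%s_%02d", sex,
                                                 seq_len(nS))))
        lens <- chains$end - chains$start + 1 -
            vapply(seq_len(nI), function(i)
                sum(chains$intron_ends[[i]] - chains$intron_starts[[i]] + 1),
                0)
        seIso <- SexExperiment(counts, lengths = pmax(lens, 1), sex = sex)
        list(chains = chains, truth = truth, counts = seIso,
             truthCounts = data.frame(
                 isoform_id = chains$isoform_id[biasIdx],
                 log2fc_male_vs_female = biasSign * config$isoformLog2fc))
    })
}
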