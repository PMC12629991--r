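test_that("knee threshold falls between the levels of a step profile", {
    reach <- c(Inf, rep(0.1, 500), rep(2, 20))
    thr <- kneeThreshold(reach)
    expect_gt(thr, 0.1)
    expect_lt(thr, 2)
})

test_that("clustering recovers planted regimes and is deterministic", {
    sim <- simulateRegionProfiles(nPerClass = 120L, seed = 77)
    cl <- clusterRegions(sim$fractions, seed = 7)
    lab <- clusterLabels(cl)
    reg <- sim$truth != "noise"
    skip_if_not_installed("mclust")
    ari <- mclust::adjustedRandIndex(lab[reg], sim$truth[reg])
    expect_gte(ari, 0.9)
    # deterministic under the same seed
    cl2 <- clusterRegions(sim$fractions, seed = 7)
    expect_identical(clusterLabels(cl2), lab)
    # duplicate rows always share a label
    m <- sim$fractions
    m[2, ] <- m[1, ]
    cl3 <- clusterRegions(m, seed = 7)
    expect_equal(clusterLabels(cl3)[1], clusterLabels(cl3)[2])
    # too few regions refused
    expect_error(clusterRegions(sim$fractions[1:50, ], seed = 1),
                 "too few")
})

mkRegions <- function(fractions, totalRaw) {
    gr <- GenomicRanges::GRanges(
        paste0("tx", seq_len(nrow(fractions))),
        IRanges::IRanges(1, 100))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        regionId = paste0("r", seq_len(nrow(fractions))),
        meanSmoothed = NA_real_, totalRaw = totalRaw,
        cluster = NA_character_)
    new("GermRegions", ranges = gr, kmerFractions = fractions)
}

test_that("representative k-mers are the minimal covering prefix", {
    # one k-mer carrying 60% of the multivalency: the set is exactly it
    fr <- matrix(c(0.6, 0.3, 0.1), 1, dimnames = list(NULL,
                 c("AAAAA", "CCCCC", "GGGGG")))
    reg <- mkRegions(fr, 10)
    rk <- representativeKmers(reg, classes = 1L)
    expect_equal(rk[["1"]], "AAAAA")
    # minimal-prefix property on pooled masses
    set.seed(79)
    fr <- matrix(rexp(5 * 20), 5)
    fr <- fr / rowSums(fr)
    colnames(fr) <- apply(expand.grid(rep(list(c("A", "C", "G", "T")),
                                          2))[1:20, ], 1,
                          function(r) paste0(paste(r, collapse = ""), "AAA"))
    reg <- mkRegions(fr, rep(1, 5))
    rk <- representativeKmers(reg, classes = rep(1L, 5))[["1"]]
    mass <- colSums(fr) / sum(fr)
    expect_gte(sum(mass[rk]), 0.5)
    expect_lt(sum(mass[rk[-length(rk)]]), 0.5)
    # a pure AG repeat cluster is represented by its two alternating k-mers
    s <- strrep("AG", 150)
    f2 <- kmerContributionFractions(s, germScore(s), 0, nchar(s))
    m2 <- matrix(0, 2, length(f2), dimnames = list(NULL, names(f2)))
    m2[1, ] <- f2; m2[2, ] <- f2
    rk <- representativeKmers(mkRegions(m2, c(1, 1)), rep(1L, 2))
    expect_true(all(rk[["1"]] %in% c("AGAGA", "GAGAG")))
})

test_that("deduplication keeps a shared k-mer in one cluster only", {
    fr <- rbind(c(0.55, 0.25, 0.20, 0),
                c(0.35, 0.05, 0.20, 0.40))
    colnames(fr) <- c("AAAAA", "CCCCC", "GGGGG", "TTTTT")
    reg <- mkRegions(fr, c(1, 1))
    rk <- representativeKmers(reg, classes = c(1L, 2L), dedupe = TRUE)
    shared <- intersect(rk[["1"]], rk[["2"]])
    expect_length(shared, 0)
    # AAAAA contributes more to cluster 1, so it stays there
    expect_true("AAAAA" %in% rk[["1"]])
})

test_that("transcript class scores reward class k-mers in multivalent context", {
    set.seed(83)
    sim <- simulateTranscriptome(simulationConfig(nGenes = 40L,
                                                  plantedFraction = 0.25,
                                                  classes = "GA"),
                                 seed = 83)
    tr <- scoreTranscripts(sim$models)
    s <- strrep("AG", 100)
    repK <- list(GA = names(kmerContributionFractions(s, germScore(s),
                                                      0, nchar(s))))
    repK$GA <- unique(c(repK$GA, "AGAAG", "GAAGA", "AAGAG", "AGAGA",
                        "GAGAA", "AAGAA", "AGAAA", "GAAAG", "AAAGA"))
    sc <- transcriptClassScores(sim$models, tr, repK)
    planted <- sim$truth$txId[!is.na(sim$truth$class)]
    expect_gt(min(sc$GA[sc$txId %in% planted]),
              max(sc$GA[!sc$txId %in% planted]))
    # a transcript without any class k-mers scores 0
    noGa <- c(z = strrep("CTC", 100))
    models2 <- new("TranscriptModels",
                   seqs = Biostrings::DNAStringSet(noGa), geneId = "z",
                   exonLengths = list(c(100L, 200L)), cdsStart = 0L,
                   cdsEnd = 300L, spliced = TRUE)
    tr2 <- scoreTranscripts(models2)
    sc2 <- suppressMessages(transcriptClassScores(models2, tr2, repK))
    expect_equal(sc2$GA, 0)
})

test_that("retention features have the documented geometry and scaling", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 30L), seed = 89)
    tr <- scoreTranscripts(sim$models)
    repK <- list(GA = c("AGAAG", "GAAGA"), C = c("CCCCC", "CCTCC"))
    ft <- retentionFeatures(sim$models, tr, repK)
    expect_equal(ft$cdsLength,
                 cdsEnd(sim$models) - cdsStart(sim$models),
                 ignore_attr = TRUE)
    expect_equal(ft$meanExonLength,
                 vapply(exonLengths(sim$models), mean, 0),
                 ignore_attr = TRUE)
    expect_equal(mean(ft$GA), 0, tolerance = 1e-12)
    expect_equal(sd(ft$GA), 1, tolerance = 1e-12)
    # merging clusters unions their k-mer sets into one feature
    ftm <- retentionFeatures(sim$models, tr, repK,
                             mergeClusters = list(GC = c("GA", "C")))
    expect_true("GC" %in% names(ftm))
    expect_false(any(c("GA", "C") %in% names(ftm)))
})
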