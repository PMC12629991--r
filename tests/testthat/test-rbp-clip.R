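test_that("motif z-scores and the tail test behave as documented", {
    r <- c(rep(1, 20), 10)
    names(r) <- c(replicate(20, paste(sample(c("A", "C", "G", "U"), 5,
                                             TRUE), collapse = "")), "AGAAG")
    tab <- motifZscores(setNames(as.numeric(r), names(r)))
    out <- tab[tab$kmer == "AGAAG", ]
    expect_gt(out$z, 4)
    expect_lt(out$p, 0.05)
    expect_true(out$significant)
    expect_false(any(tab$significant[tab$kmer != "AGAAG"]))
    expect_equal(mean(tab$z), 0, tolerance = 1e-12)
    # all scores at the mean: z = 0, p = 0.5, nothing selected
    expect_error(motifZscores(data.frame(kmer = c("AAAAA", "CCCCC"),
                                         rScore = c(2, 2))), "distinct")
    # significance is p < 0.05, boundary excluded
    expect_identical(tab$significant, tab$p < 0.05)
})

test_that("binding potential is a hand-countable weighted motif sum", {
    tab <- data.frame(kmer = c("AGAAG", "CCCCC"), rScore = c(3, 1),
                      z = c(3, -1), p = c(0.001, 0.9),
                      significant = c(TRUE, FALSE))
    # AGAAG occurs twice in the rolling 5-mers of AGAAGAAGA
    expect_equal(bindingPotential("AGAAGAAGA", tab), 2 * 3,
                 ignore_attr = TRUE)
    # no significant motifs present: score 0
    expect_equal(bindingPotential("CCCCCCCC", tab), 0, ignore_attr = TRUE)
    # short sequence: 0
    expect_equal(bindingPotential("AG", tab), 0, ignore_attr = TRUE)
    # additive under concatenation up to boundary effects
    s1 <- "AGAAGAAGA"; s2 <- "CCCAGAAGC"
    joint <- bindingPotential(paste0(s1, s2), tab)
    parts <- bindingPotential(s1, tab) + bindingPotential(s2, tab)
    boundary <- paste0(substr(s1, nchar(s1) - 3, nchar(s1)),
                       substr(s2, 1, 4))
    expect_equal(joint, parts + bindingPotential(boundary, tab),
                 ignore_attr = TRUE)
})

test_that("within-k-mer percentiles centre at 50 and handle singletons", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 10L,
                                                  plantedFraction = 0),
                                 seed = 91)
    tr <- scoreTranscripts(sim$models)
    pct <- kmerGermPercentiles(sim$models, tr)
    expect_true(all(pct$percentile > 0 & pct$percentile < 100))
    means <- tapply(pct$percentile, pct$kmer, mean)
    expect_equal(as.numeric(means), rep(50, length(means)),
                 tolerance = 1e-9)
    singles <- names(which(table(pct$kmer) == 1))
    if (length(singles))
        expect_equal(pct$percentile[pct$kmer %in% singles],
                     rep(50, length(singles)))
})

test_that("CLIP sample QC drops bottom thirds and zero-CDS samples", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 6L,
                                                  plantedFraction = 0),
                                 seed = 93)
    mk <- function(id, cdsCount, utrCount) {
        cs <- cdsStart(sim$models)[1]
        rbind(data.frame(txId = txId(sim$models)[1], pos = cs + 0:9,
                         count = rep(cdsCount %/% 10, 10), sampleId = id),
              data.frame(txId = txId(sim$models)[1], pos = 0:9,
                         count = rep(utrCount %/% 10, 10), sampleId = id))
    }
    xl <- rbind(mk("goodHigh", 9000, 100), mk("goodMid", 4000, 100),
                mk("lowProp", 1000, 9000), mk("lowCount", 300, 10),
                mk("zeroCds", 0, 500), mk("goodHigh2", 8000, 200))
    expect_message(out <- filterClipSamples(xl, sim$models), "zero CDS")
    kept <- attr(out, "samples")
    expect_false("zeroCds" %in% kept)
    expect_false("lowProp" %in% kept)    # bottom third by CDS proportion
    expect_false("lowCount" %in% kept)   # then bottom third by CDS count
    expect_setequal(kept, c("goodHigh", "goodMid", "goodHigh2"))
})

test_that("uniform crosslinking is calibrated at ratio 1; planted RBP passes", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 40L,
                                                  plantedFraction = 0.2),
                                 seed = 95)
    tr <- scoreTranscripts(sim$models)
    pct <- kmerGermPercentiles(sim$models, tr)
    ratios <- vapply(1:8, function(s) {
        xl <- simulateCrosslinks(sim, "u", "uniform", totalCounts = 1e4,
                                 seed = 900 + s)
        clipMultivalencyPreference(xl, sim$models, tr,
                                   percentiles = pct)$ratio
    }, 0)
    expect_equal(mean(ratios), 1, tolerance = 0.02)
    xl <- simulateCrosslinks(sim, "e", "region", factor = 5,
                             totalCounts = 1e4, seed = 777)
    pref <- clipMultivalencyPreference(xl, sim$models, tr,
                                       percentiles = pct)
    expect_gte(pref$ratio, 1.1)
    expect_true(pref$passes)
})

test_that("region crosslink enrichment recovers planted factors", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 40L,
                                                  plantedFraction = 0.3),
                                 seed = 97)
    reg <- truthRegions(sim)
    xl <- simulateCrosslinks(sim, "s", "region", factor = 5,
                             totalCounts = 1e5, seed = 55)
    enr <- regionCrosslinkEnrichment(xl, reg, sim$models)
    expect_equal(mean(enr$byRegion$ratio), 5, tolerance = 0.1)
    # uniform null sits at 1
    xl0 <- simulateCrosslinks(sim, "s0", "uniform", totalCounts = 1e5,
                              seed = 56)
    enr0 <- regionCrosslinkEnrichment(xl0, reg, sim$models)
    expect_equal(mean(enr0$byRegion$ratio), 1, tolerance = 0.05)
    # crosslinks only inside a region: skipped without pseudocount,
    # finite with one
    one <- sim$truth[!is.na(sim$truth$class), ][1, ]
    xin <- data.frame(txId = one$txId,
                      pos = one$regionStart + 0:4, count = 10L,
                      sampleId = "only")
    enrSkip <- regionCrosslinkEnrichment(xin, reg, sim$models,
                                         pseudocount = 0,
                                         topHalfFilter = FALSE)
    expect_equal(nrow(enrSkip$byRegion), 0L)
    enrPs <- regionCrosslinkEnrichment(xin, reg, sim$models,
                                       pseudocount = 0.5,
                                       topHalfFilter = FALSE)
    hit <- enrPs$byRegion[enrPs$byRegion$ratio > 0, ]
    expect_equal(nrow(hit), 1L)
    expect_true(is.finite(hit$ratio) && hit$ratio > 10)
})

test_that("metaprofiles are per-region, per-million normalized", {
    sim <- simulateTranscriptome(simulationConfig(nGenes = 10L,
                                                  plantedFraction = 0.2),
                                 seed = 99)
    reg <- truthRegions(sim)[1]
    gr <- regionRanges(reg)
    mid <- floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
    tx <- as.character(GenomicRanges::seqnames(gr))
    # a single crosslink at the midpoint of the region, 1M total crosslinks
    other <- setdiff(txId(sim$models), tx)[1]
    xl <- rbind(data.frame(txId = tx, pos = mid, count = 1L,
                           sampleId = "s"),
                data.frame(txId = other, pos = 2000L, count = 999999L,
                           sampleId = "s"))
    prof <- regionMetaprofile(xl, reg, halfwidth = 50L)
    expect_equal(prof$value[prof$relPos == 0], 1)
    expect_equal(sum(prof$value), 1)
    # doubling all counts leaves the profile unchanged
    xl2 <- xl; xl2$count <- xl2$count * 2L
    prof2 <- regionMetaprofile(xl2, reg, halfwidth = 50L)
    expect_equal(prof2$value, prof$value)
})
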