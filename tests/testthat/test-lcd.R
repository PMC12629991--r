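test_that("window entropy matches direct formula evaluation", {
    expect_equal(windowEntropy(strrep("A", 41)), 0)
    # 21 of one residue + 20 of another
    w <- paste0(strrep("A", 21), strrep("L", 20))
    expected <- -(21 / 41 * log2(21 / 41) + 20 / 41 * log2(20 / 41))
    expect_equal(windowEntropy(w), expected, tolerance = 1e-9)
    expect_equal(expected, 0.9995708, tolerance = 1e-6)
    # permutation invariance within the window
    set.seed(61)
    p <- paste(sample(strsplit(w, "")[[1]]), collapse = "")
    expect_equal(windowEntropy(p), windowEntropy(w))
    # evenness maximizes entropy
    uniform <- paste(rep(LETTERS[1:20], length.out = 41), collapse = "")
    expect_gt(windowEntropy(uniform), windowEntropy(w))
    # shorter than the window: empty
    expect_length(windowEntropy("MKR"), 0)
})

test_that("LCD calling recovers a planted poly-Q stretch", {
    set.seed(67)
    aaPool <- c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K", "M",
                "F", "P", "S", "T", "W", "Y", "V")
    randomProt <- function(n) paste(sample(aaPool, n, TRUE), collapse = "")
    prots <- c(setNames(vapply(1:30, function(i) randomProt(400), ""),
                        paste0("p", 1:30)),
               polyq = paste0(randomProt(150), strrep("Q", 80),
                              randomProt(150)))
    lcds <- callLcds(prots)
    hit <- lcds[lcds$proteinId == "polyq", ]
    expect_equal(nrow(hit), 1L)
    expect_lte(hit$start, 150)
    expect_gte(hit$end, 230)
    expect_equal(hit$minEntropy, 0)
})

test_that("non-overlapping sub-threshold spans stay separate domains", {
    prot <- c(two = paste0(strrep("A", 45), "W", strrep("P", 45)))
    lcds <- callLcds(prot, threshold = 0.1)
    expect_equal(nrow(lcds), 2L)
    expect_equal(lcds$start, c(0L, 46L))
    expect_equal(lcds$end, c(45L, 91L))
})

test_that("the percentile rule marks about 2% of windows on random input", {
    set.seed(71)
    aaPool <- LETTERS[1:20]
    prots <- setNames(vapply(1:40, function(i)
        paste(sample(aaPool, 500, TRUE), collapse = ""), ""),
        paste0("p", 1:40))
    ent <- unlist(lapply(prots, windowEntropy))
    thr <- attr(callLcds(prots), "threshold")
    frac <- mean(ent <= thr)
    expect_gt(frac, 0.01)
    expect_lt(frac, 0.04)
})

test_that("R-LCD / R-MCD thresholds fall on the documented side", {
    # whole-protein domains via an explicit permissive threshold
    mk <- function(aa) setNames(paste(aa, collapse = ""), "p")
    classify <- function(aa) callLcds(mk(aa), window = 41L, threshold = Inf)
    # exactly 20% arginine: R-LCD (>=), but 24% charged: not an R-MCD
    d <- classify(c(rep("R", 10), rep("E", 2), rep("G", 38)))
    expect_true(d$isRLcd); expect_false(d$isRMcd)
    # 52% charged, net +10: both flags
    d <- classify(c(rep("R", 12), rep("K", 6), rep("E", 8), rep("G", 24)))
    expect_true(d$isRLcd); expect_true(d$isRMcd)
    # exactly 40% charged is not enough (> required)
    d <- classify(c(rep("R", 10), rep("K", 8), rep("G", 27)))
    expect_equal(d$chargedFraction, 0.4)
    expect_false(d$isRMcd)
    # net charge exactly 0 is not enough (> required)
    d <- classify(c(rep("R", 11), rep("E", 11), rep("G", 22)))
    expect_equal(d$netCharge, 0L)
    expect_true(d$chargedFraction > 0.4)
    expect_false(d$isRMcd)
    # no arginine: neither flag
    d <- classify(c(rep("K", 12), rep("G", 29)))
    expect_false(d$isRLcd); expect_false(d$isRMcd)
})

test_that("arginine codon usage separates planted GA and CG regimes", {
    set.seed(73)
    mk <- function(cls) paste(c("ATG", germkit:::.plantedCodons(cls, 120, 0.9),
                                "TAA"), collapse = "")
    cdss <- c(setNames(vapply(1:30, function(i) mk("GA"), ""),
                       paste0("ga", 1:30)),
              setNames(vapply(1:30, function(i) mk("GC"), ""),
                       paste0("gc", 1:30)))
    prot <- translateCds(cdss)
    lcds <- data.frame(proteinId = names(prot), start = 0L,
                       end = nchar(prot), isRLcd = TRUE)
    au <- arginineCodonUsage(lcds, cdss)
    expect_equal(unname(rowSums(au$usage)), rep(1, nrow(au$usage)))
    # within-regime positive, cross-regime negative correlations
    ga <- c("AGA", "AGG", "CGA"); cg <- c("CGG", "CGC")
    expect_gt(min(au$correlation[ga, ga][upper.tri(diag(3))]), 0)
    expect_gt(au$correlation["CGG", "CGC"], 0)
    expect_lt(max(au$correlation[ga, cg]), 0)
    # PC1 thirds recover the planted labels
    truthCls <- ifelse(grepl("^ga", names(prot)), "GA_rich", "CG_rich")
    assigned <- au$class != "unassigned"
    expect_gte(mean(au$class[assigned] == truthCls[assigned]), 0.95)
    # degenerate inputs
    oneCodon <- c(p1 = "ATGAGAAGATAA")
    expect_error(arginineCodonUsage(
        data.frame(proteinId = "p1", start = 0L, end = 3L, isRLcd = TRUE),
        oneCodon), "at least 3")
    # an LCD using only AGA has the unit proportion vector
    lcds3 <- data.frame(proteinId = c("a", "b", "c"), start = 0L, end = 3L,
                        isRLcd = TRUE)
    cds3 <- c(a = "AGAAGAAGA", b = "CGGCGGCGG", c = "AGACGGCGC")
    lcds3$end <- 3L
    au3 <- suppressWarnings(arginineCodonUsage(lcds3, cds3))
    expect_equal(unname(au3$usage["a:0-3", ]), c(1, 0, 0, 0, 0, 0))
})
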