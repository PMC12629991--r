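test_that("parameter validity is enforced", {
    p <- GermParams()
    expect_equal(germWindow(p), 62L)
    expect_equal(kmerLength(p), 5L)
    expect_error(GermParams(n = 124L), "odd")
    expect_error(GermParams(k = 62L, n = 123L), "exceed")
    expect_error(GermParams(lambda = 0), "positive")
})

test_that("edge cases: short sequences and N handling", {
    expect_length(germScore("ACG"), 0)            # shorter than k
    expect_equal(germScore("ACGTA"), 0)           # single k-mer, no neighbours
    # a central k-mer containing N scores 0; N neighbours contribute nothing
    s <- paste0(strrep("A", 30), "N", strrep("A", 30))
    g <- germScore(s)
    expect_true(all(g[27:31] == 0))               # k-mers covering the N
    expect_error(germScore("ACGTX"), "alphabet")
    # U is canonicalized to T
    expect_equal(germScore(strrep("GU", 50)), germScore(strrep("GT", 50)))
})

test_that("homopolymer interior score matches the closed form", {
    g <- germScore(strrep("A", 400))
    w <- 62
    closed <- 2 * sum((w - (5:62)) / w)   # all neighbours identical, d = 0
    expect_equal(g[200], closed, tolerance = 1e-12)
})

test_that("optimized scorer equals the literal oracle on random sequences", {
    set.seed(101)
    for (i in 1:20) {
        s <- randomDna(sample(150:600, 1))
        expect_lt(max(abs(germScore(s) - germScoreOracle(s))), 1e-9)
    }
    # and for the literal asymmetric weight variant
    s <- randomDna(300)
    expect_lt(max(abs(germScore(s, weightScheme = "literal") -
                      germScoreOracle(s, weight = "literal"))), 1e-9)
    expect_gt(max(abs(germScore(s) -
                      germScore(s, weightScheme = "literal"))), 0)
})

test_that("a pure GA repeat outscores composition-matched shuffles", {
    set.seed(7)
    ga <- strrep("GA", 150)
    mga <- mean(germScore(ga))
    chars <- strsplit(ga, "")[[1]]
    for (i in 1:50) {
        sh <- paste(sample(chars), collapse = "")
        expect_gt(mga, mean(germScore(sh)))
    }
})

test_that("interior scores depend only on the surrounding window", {
    set.seed(11)
    core <- randomDna(2 * 62 + 5 - 1)             # 2w + k - 1 nt
    s1 <- paste0(randomDna(80), core, randomDna(80))
    s2 <- paste0(randomDna(120), core, randomDna(40))
    # score of the k-mer at the centre of `core` in each embedding
    c1 <- 80 + 62; c2 <- 120 + 62                 # 0-based centre starts
    expect_equal(germScore(s1)[c1 + 1], germScore(s2)[c2 + 1])
})

test_that("reverse complementation mirrors, not preserves, the track", {
    set.seed(13)
    s <- paste0(strrep("GA", 60), randomDna(200))
    g <- germScore(s)
    grc <- germScore(revcomp(s))
    # per-position scores differ between the strands of an asymmetric
    # sequence (scoring the wrong strand gives the wrong profile) ...
    expect_false(isTRUE(all.equal(g, grc)))
    # ... but complementation preserves Hamming distances and reversal
    # mirrors the symmetric weights, so the track is exactly mirrored
    expect_equal(g, rev(grc))
    # the literal asymmetric weight breaks even the mirror symmetry
    gl <- germScore(s, weightScheme = "literal")
    grcl <- germScore(revcomp(s), weightScheme = "literal")
    expect_false(isTRUE(all.equal(gl, rev(grcl))))
})

test_that("normalization maps pooled min to 0 and median to 1", {
    tr <- new("GermTracks", txId = c("a", "b"),
              raw = list(c(0, 2), c(4, 2, 0)), normalized = list(),
              smoothed = list(), params = GermParams(), stats = NULL)
    st <- fitNormalization(tr)
    expect_equal(applyNormalization(c(0, 2, 4), st), c(0, 1, 2))
    tr <- applyNormalization(tr, st)
    pooled <- unlist(normalizedScores(tr))
    expect_identical(min(pooled), 0)
    expect_identical(median(pooled), 1)
    # affine: order statistics unchanged; no clipping outside the fit set
    set.seed(3)
    x <- runif(100, 0, 10)
    expect_identical(order(applyNormalization(x, st)), order(x))
    expect_lt(applyNormalization(-5, st), 0)
    # degenerate distribution refused
    trc <- new("GermTracks", txId = "a", raw = list(rep(1, 10)),
               normalized = list(), smoothed = list(),
               params = GermParams(), stats = NULL)
    expect_error(fitNormalization(trc), "degenerate")
})

test_that("smoothing is a truncated-window centred mean", {
    expect_equal(smoothTrack(rep(3, 200), 123L), rep(3, 200))
    v <- numeric(400); v[200] <- 1
    sv <- smoothTrack(v, 123L)
    expect_equal(sv[200], 1 / 123)
    expect_equal(sum(sv[139:261] > 0), 123)       # plateau width
    # linearity
    set.seed(5)
    a <- rnorm(300); b <- rnorm(300)
    expect_equal(smoothTrack(a + b, 41L),
                 smoothTrack(a, 41L) + smoothTrack(b, 41L))
    # edge rule: mean over in-bounds values only
    expect_equal(smoothTrack(c(1, 0, 0, 0, 0), 5L)[1], 1 / 3)
    expect_length(smoothTrack(numeric(0), 5L), 0)
})

test_that("the full pipeline populates tracks and per-nucleotide views", {
    set.seed(17)
    seqs <- setNames(vapply(1:5, function(i) randomDna(300), ""),
                     paste0("t", 1:5))
    tr <- germTracks(seqs)
    expect_length(normalizedScores(tr), 5)
    expect_length(smoothedScores(tr), 5)
    expect_equal(lengths(rawScores(tr)), lengths(smoothedScores(tr)),
                 ignore_attr = TRUE)
    pn <- perNucleotide(rawScores(tr)[[1]], 5L)
    expect_length(pn, 300)
    expect_equal(pn[297:300], rep(pn[296], 4))
})
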