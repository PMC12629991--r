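# Literal term-by-term implementation of the multivalency score, kept
# deliberately naive and independent of the package's compiled scorer.
germScoreOracle <- function(seq, k = 5L, n = 123L, lambda = 1,
                            weight = c("symmetric", "literal")) {
    weight <- match.arg(weight)
    w <- (n + 1L) %/% 2L
    s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
    enc <- match(s, c("A", "C", "G", "T", "N")) - 1L
    L <- length(enc)
    np <- L - k + 1L
    if (np < 1L) return(numeric(0))
    E <- t(vapply(1:np, function(p) enc[p:(p + k - 1L)], integer(k)))
    valid <- apply(E, 1L, function(r) all(r < 4L))
    g <- numeric(np)
    offsets <- c(-(w:k), k:w)
    for (p in 1:np) {
        if (!valid[p]) next
        tot <- 0
        for (i in offsets) {
            q <- p + i
            if (q < 1 || q > np || !valid[q]) next
            d <- sum(E[p, ] != E[q, ])
            wt <- if (weight == "symmetric") (w - abs(i)) / w
                  else abs(w - i) / w
            tot <- tot + exp(-lambda * d) * wt
        }
        g[p] <- tot
    }
    g
}

# Full-transcript-rescore oracle for codon-support ratios: rebuilds the
# mutated transcript and rescores it from scratch with the public scorer.
codonRatioRescoreOracle <- function(cds, ratios, params = GermParams()) {
    k <- kmerLength(params)
    L <- nchar(cds)
    vapply(seq_len(nrow(ratios)), function(r) {
        pos <- ratios$pos[r]
        s0 <- max(0L, pos - k + 1L)
        s1 <- min(L - k, pos)
        nat <- max(germScore(cds, params)[(s0 + 1L):(s1 + 1L)])
        alts <- strsplit(ratios$alternatives[r], ",", fixed = TRUE)[[1]]
        mut <- mean(vapply(alts, function(b) {
            m <- cds
            substr(m, pos + 1L, pos + 1L) <- b
            max(germScore(m, params)[(s0 + 1L):(s1 + 1L)])
        }, 0))
        nat / mut
    }, 0)
}

# Draw a toy CDS whose synonymous search space is small enough to
# enumerate exhaustively.
sampleToyCds <- function(nCodons, maxSpace = 2e5) {
    gc <- Biostrings::GENETIC_CODE
    repeat {
        aa <- sample(c("K", "E", "R", "G", "S", "P", "L", "Q"), nCodons,
                     replace = TRUE)
        space <- prod(vapply(aa, function(a) sum(gc == a), 0))
        if (space <= maxSpace) break
    }
    paste(vapply(aa, function(a) sample(names(gc)[gc == a], 1), ""),
          collapse = "")
}

# Exhaustive search over all synonymous recodings of a tiny CDS.
recodeExhaustive <- function(cds, objective, gcTolerance = 0.02) {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    gc <- Biostrings::GENETIC_CODE
    syn <- lapply(codons, function(cd) names(gc)[gc == gc[[cd]]])
    gc0 <- sum(strsplit(cds, "")[[1]] %in% c("G", "C")) / nchar(cds)
    grid <- expand.grid(syn, stringsAsFactors = FALSE)
    vals <- apply(grid, 1L, function(row) {
        s <- paste(row, collapse = "")
        gcf <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
        if (abs(gcf - gc0) > gcTolerance) return(NA_integer_)
        countAGOnlyKmers(s)
    })
    if (objective == "minimize") min(vals, na.rm = TRUE)
    else max(vals, na.rm = TRUE)
}
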