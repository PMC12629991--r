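#' @include codon.R
NULL

#' Sliding-window amino-acid entropy
#'
#' Shannon entropy (bits) of the amino-acid composition in a sliding window
#' along a protein — the low-complexity signal. Permutation-invariant
#' within a window; 0 for a homopolymeric window; maximal for a uniform
#' composition.
#'
#' @param protein protein sequence (character or AAString).
#' @param window window size in amino acids (default 41).
#' @return numeric vector, one value per window start (length
#'   `L - window + 1`); empty when the protein is shorter than the window.
#' @export
windowEntropy <- function(protein, window = 41L) {
    if (is(protein, "XString")) protein <- as.character(protein)
    s <- strsplit(protein, "", fixed = TRUE)[[1]]
    L <- length(s)
    if (L < window) return(numeric(0))
    code <- match(s, LETTERS)
    if (anyNA(code)) stop("protein contains characters outside A-Z")
    nW <- L - window + 1L
    counts <- tabulate(code[seq_len(window)], nbins = 26L)
    # H = log2(W) - (1/W) * sum n log2 n, updated incrementally
    nlogn <- function(n) ifelse(n > 0L, n * log2(n), 0)
    S <- sum(nlogn(counts))
    out <- numeric(nW)
    out[1L] <- log2(window) - S / window
    if (nW > 1L) for (i in 2L:nW) {
        dropC <- code[i - 1L]; addC <- code[i + window - 1L]
        if (dropC != addC) {
            S <- S - nlogn(counts[dropC]) - nlogn(counts[addC])
            counts[dropC] <- counts[dropC] - 1L
            counts[addC] <- counts[addC] + 1L
            S <- S + nlogn(counts[dropC]) + nlogn(counts[addC])
        }
        out[i] <- log2(window) - S / window
    }
    pmax(out, 0)
}

.CHARGED <- c("D", "E", "K", "R")

#' Call low-complexity domains over a proteome
#'
#' Pools the sliding-window entropies of all proteins and thresholds at the
#' stated percentile (bottom 2% by default). Every sub-threshold window
#' contributes its full span, overlapping spans are merged, and each
#' resulting domain is annotated with its composition: arginine fraction,
#' charged-residue fraction (D, E, K, R; histidine excluded), net charge
#' (K + R - D - E), and the R-LCD / R-MCD flags
#' (`isRLcd`: arginine fraction >= 0.20; `isRMcd`: additionally net charge
#' > 0 and charged fraction > 0.40).
#'
#' @param proteins named character vector (or AAStringSet) of protein
#'   sequences. Proteins shorter than the window are skipped with a
#'   message.
#' @param window entropy window in amino acids (default 41).
#' @param percentile bottom percentile defining low complexity (default 2).
#' @param threshold optional explicit entropy threshold (bits), overriding
#'   the percentile rule (e.g. to reuse a threshold fitted on another
#'   proteome).
#' @return data frame with one row per domain: `proteinId`, 0-based
#'   half-open `start`/`end` (amino-acid coordinates), `minEntropy`,
#'   `argFraction`, `chargedFraction`, `netCharge`, `isRLcd`, `isRMcd`.
#'   The threshold used is attached as `attr(, "threshold")`.
#' @export
callLcds <- function(proteins, window = 41L, percentile = 2,
                     threshold = NULL) {
    if (is(proteins, "AAStringSet")) {
        nm <- names(proteins)
        proteins <- setNames(as.character(proteins), nm)
    }
    ent <- lapply(proteins, windowEntropy, window = window)
    short <- lengths(ent) == 0L
    if (any(short))
        message(sum(short), " protein(s) shorter than the window skipped")
    pooled <- unlist(ent, use.names = FALSE)
    if (is.null(threshold)) {
        if (length(unique(pooled)) < 2L)
            stop("degenerate pooled entropy distribution")
        threshold <- quantile(pooled, percentile / 100, names = FALSE, type = 7)
    }
    rows <- list()
    for (id in names(proteins)[!short]) {
        e <- ent[[id]]
        sub <- which(e <= threshold)
        if (!length(sub)) next
        iv <- cbind(sub - 1L, sub - 1L + window)   # 0-based half-open spans
        iv <- .mergeByOverlap(iv, 1L)
        s <- strsplit(proteins[[id]], "", fixed = TRUE)[[1]]
        for (j in seq_len(nrow(iv))) {
            a0 <- iv[j, 1L]; a1 <- iv[j, 2L]
            inWin <- sub[sub - 1L >= a0 & sub - 1L + window <= a1]
            aa <- s[(a0 + 1L):a1]
            argF <- mean(aa == "R")
            chF <- mean(aa %in% .CHARGED)
            net <- sum(aa %in% c("K", "R")) - sum(aa %in% c("D", "E"))
            isRL <- argF >= 0.20
            rows[[length(rows) + 1L]] <- data.frame(
                proteinId = id, start = a0, end = a1,
                minEntropy = min(e[inWin]), argFraction = argF,
                chargedFraction = chF, netCharge = net,
                isRLcd = isRL,
                isRMcd = isRL && net > 0L && chF > 0.40)
        }
    }
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(proteinId = character(0), start = integer(0),
                           end = integer(0), minEntropy = numeric(0),
                           argFraction = numeric(0),
                           chargedFraction = numeric(0),
                           netCharge = integer(0), isRLcd = logical(0),
                           isRMcd = logical(0))
    attr(out, "threshold") <- threshold
    out
}

.ARG_CODONS <- c("AGA", "AGG", "CGA", "CGG", "CGC", "CGT")

#' Arginine codon usage across R-LCDs
#'
#' For each arginine-rich LCD (arginine fraction >= 0.20), the proportions
#' of the six arginine codons in its coding region; pairwise Spearman
#' correlations of codon usage across domains; and a principal-component
#' split: the top and bottom third of domains by PC1 are labelled
#' `GA_rich` and `CG_rich` respectively (PC1 sign is fixed so that AGA
#' loads positively, making high PC1 the GA-rich direction).
#'
#' @param lcds data frame from [callLcds()]; rows with `isRLcd == FALSE`
#'   are ignored. LCD amino-acid coordinates are mapped to CDS nucleotides
#'   as `aa i <-> nt [3i, 3i + 3)`.
#' @param cdsSet named character vector of the in-frame CDSs encoding the
#'   proteins (names matching `proteinId`).
#' @return list with `usage` (domains x 6 proportion matrix), `correlation`
#'   (6 x 6 Spearman matrix), `pc1` (scores) and `class`
#'   (`GA_rich` / `CG_rich` / `unassigned` per domain). Refused with an
#'   error when fewer than 3 R-LCDs are available.
#' @export
arginineCodonUsage <- function(lcds, cdsSet) {
    r <- lcds[lcds$isRLcd, , drop = FALSE]
    if (nrow(r) < 3L)
        stop("need at least 3 R-LCDs for correlation/PCA (got ", nrow(r), ")")
    usage <- matrix(0, nrow(r), length(.ARG_CODONS),
                    dimnames = list(sprintf("%s:%d-%d", r$proteinId, r$start,
                                            r$end), .ARG_CODONS))
    for (j in seq_len(nrow(r))) {
        cds <- cdsSet[[r$proteinId[j]]]
        codons <- .codonsOf(cds)[(r$start[j] + 1L):r$end[j]]
        argc <- codons[codons %in% .ARG_CODONS]
        if (!length(argc))
            stop("R-LCD ", rownames(usage)[j], " has no arginine codons")
        tt <- table(factor(argc, levels = .ARG_CODONS))
        usage[j, ] <- as.numeric(tt) / sum(tt)
    }
    corr <- cor(usage, method = "spearman")
    pca <- prcomp(usage, center = TRUE, scale. = FALSE)
    pc1 <- pca$x[, 1L]
    if (pca$rotation["AGA", 1L] < 0) pc1 <- -pc1
    qs <- quantile(pc1, c(1 / 3, 2 / 3), names = FALSE)
    cls <- rep("unassigned", length(pc1))
    cls[pc1 >= qs[2L]] <- "GA_rich"
    cls[pc1 <= qs[1L]] <- "CG_rich"
    list(usage = usage, correlation = corr, pc1 = pc1,
         class = setNames(cls, rownames(usage)))
}
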