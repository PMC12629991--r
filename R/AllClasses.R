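#' GeRM scoring parameters
#'
#' Holds the constants of the GeRM (Generalized RNA Multivalency) score: the
#' k-mer length `k`, the window size `n` (odd, in nucleotides) from which the
#' half-window `w = (n + 1) / 2` is derived, the similarity decay constant
#' `lambda`, and the width of the moving-average smoothing window.
#'
#' For a k-mer starting at position `p`, the raw score sums
#' `exp(-lambda * Hamming(A0, Ai)) * weight(i)` over neighbour k-mer offsets
#' `i` with `k <= |i| <= w`; k-mers overlapping the centre are ignored and
#' positions outside the transcript contribute 0.
#'
#' @slot k k-mer length in nucleotides.
#' @slot n window size in nucleotides (odd, greater than `2 * k`).
#' @slot lambda similarity decay constant (dimensionless, positive).
#' @slot smoothWidth width of the moving-average smoothing window (odd).
#' @export
setClass("GermParams",
    representation(k = "integer", n = "integer", lambda = "numeric",
                   smoothWidth = "integer"))

setValidity("GermParams", function(object) {
    msg <- character()
    if (length(object@k) != 1L || object@k < 1L)
        msg <- c(msg, "'k' must be a single positive integer")
    if (length(object@n) != 1L || object@n %% 2L != 1L)
        msg <- c(msg, "'n' must be a single odd integer")
    if (length(object@n) == 1L && length(object@k) == 1L &&
        object@n <= 2L * object@k)
        msg <- c(msg, "'n' must exceed 2 * k")
    if (length(object@lambda) != 1L || object@lambda <= 0)
        msg <- c(msg, "'lambda' must be a single positive number")
    if (length(object@smoothWidth) != 1L || object@smoothWidth %% 2L != 1L)
        msg <- c(msg, "'smoothWidth' must be a single odd integer")
    if (length(msg)) msg else TRUE
})

#' @param k,n,lambda,smoothWidth see slot descriptions. Defaults are the
#'   published operating point: `k = 5`, `n = 123`, `lambda = 1`,
#'   `smoothWidth = 123`, giving a half-window `w = 62` and neighbour
#'   offsets `-62..-5` and `5..62`.
#' @return a `GermParams` object.
#' @examples
#' p <- GermParams()
#' germWindow(p)  # 62
#' @rdname GermParams-class
#' @export
GermParams <- function(k = 5L, n = 123L, lambda = 1, smoothWidth = 123L) {
    new("GermParams", k = as.integer(k), n = as.integer(n),
        lambda = as.numeric(lambda), smoothWidth = as.integer(smoothWidth))
}

#' Pooled normalization statistics for raw GeRM scores
#'
#' Raw scores are affinely rescaled so that, on the transcript set the
#' statistics were fitted on, the pooled minimum maps to 0 and the pooled
#' median maps to 1: `x' = (x - minRaw) / (medianRaw - minRaw)`.
#'
#' @slot minRaw pooled minimum of the raw scores.
#' @slot medianRaw pooled median of the raw scores.
#' @slot provenance identifier of the transcript set used for fitting.
#' @export
setClass("NormalizationStats",
    representation(minRaw = "numeric", medianRaw = "numeric",
                   provenance = "character"))

setValidity("NormalizationStats", function(object) {
    if (object@medianRaw <= object@minRaw)
        return("pooled median must exceed pooled minimum (degenerate score distribution)")
    TRUE
})

#' Spliced transcript models
#'
#' One record per transcript: the spliced sequence in transcript (5'->3')
#' orientation, the exon length decomposition, and the CDS extent in 0-based
#' half-open spliced-transcript coordinates. All downstream coordinates in
#' the package live in this spliced-transcript space.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of spliced sequences, named by
#'   transcript id (DNA alphabet; U is canonicalized to T on input).
#' @slot geneId gene id per transcript.
#' @slot exonLengths list of integer vectors, exon lengths in 5'->3' order.
#' @slot cdsStart,cdsEnd integer vectors, 0-based half-open CDS bounds.
#' @slot spliced logical; TRUE when the annotation has >= 2 exons.
#' @export
setClass("TranscriptModels",
    representation(seqs = "DNAStringSet", geneId = "character",
                   exonLengths = "list", cdsStart = "integer",
                   cdsEnd = "integer", spliced = "logical"))

setValidity("TranscriptModels", function(object) {
    n <- length(object@seqs)
    msg <- character()
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "sequences must carry unique transcript ids as names")
    if (length(object@geneId) != n || length(object@exonLengths) != n ||
        length(object@cdsStart) != n || length(object@cdsEnd) != n ||
        length(object@spliced) != n)
        msg <- c(msg, "all slots must have one entry per transcript")
    if (!length(msg) && n > 0L) {
        L <- Biostrings::width(object@seqs)
        if (!all(vapply(object@exonLengths, sum, 0) == L))
            msg <- c(msg, "exon lengths must sum to the spliced sequence length")
        if (!all(object@cdsStart >= 0L & object@cdsStart < object@cdsEnd &
                 object@cdsEnd <= L))
            msg <- c(msg, "CDS bounds must satisfy 0 <= start < end <= length")
        if (!all((object@cdsEnd - object@cdsStart) %% 3L == 0L))
            msg <- c(msg, "CDS length must be divisible by 3")
        af <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE)
        extra <- af[, !colnames(af) %in% c("A", "C", "G", "T", "N"), drop = FALSE]
        if (any(rowSums(extra) > 0))
            msg <- c(msg, "sequence alphabet must be within {A, C, G, T, N}")
    }
    if (length(msg)) msg else TRUE
})

#' Per-transcript GeRM score tracks
#'
#' Raw, normalized and smoothed scores for a set of transcripts. All three
#' are aligned to k-mer start positions, so each vector has length
#' `L - k + 1` for a transcript of length `L`. `normalized` and `smoothed`
#' may be empty lists until [normalizeTracks()] / [smoothTracks()] are run.
#'
#' @slot txId transcript ids.
#' @slot raw,normalized,smoothed lists of numeric vectors per transcript.
#' @slot params the [GermParams] used for scoring.
#' @slot stats a [NormalizationStats] or NULL.
#' @export
setClass("GermTracks",
    representation(txId = "character", raw = "list", normalized = "list",
                   smoothed = "list", params = "GermParams", stats = "ANY"))

setValidity("GermTracks", function(object) {
    n <- length(object@txId)
    msg <- character()
    if (length(object@raw) != n)
        msg <- c(msg, "'raw' must have one track per transcript")
    if (length(object@normalized) && length(object@normalized) != n)
        msg <- c(msg, "'normalized' must be empty or match 'raw'")
    if (length(object@smoothed) && length(object@smoothed) != n)
        msg <- c(msg, "'smoothed' must be empty or match 'raw'")
    if (n && any(vapply(object@raw, function(v) any(v < 0), FALSE)))
        msg <- c(msg, "raw scores must be non-negative")
    if (length(msg)) msg else TRUE
})

#' High-multivalency CDS regions
#'
#' Contiguous intervals of a transcript whose smoothed GeRM scores exceed
#' the calling threshold, after window extension, merging and UTR
#' filtering. Ranges are stored 1-based closed (GRanges convention) with
#' the transcript id as seqname; [writeRegions()] emits 0-based half-open
#' BED-like rows.
#'
#' @slot ranges a [GenomicRanges::GRanges] with mcols `regionId`,
#'   `meanSmoothed`, `totalRaw` and `cluster`.
#' @slot kmerFractions numeric matrix, one row per region, columns named by
#'   k-mer: the fraction of the region's total raw multivalency carried by
#'   each k-mer (rows sum to 1).
#' @export
setClass("GermRegions",
    representation(ranges = "GRanges", kmerFractions = "matrix"))

setValidity("GermRegions", function(object) {
    n <- length(object@ranges)
    msg <- character()
    need <- c("regionId", "meanSmoothed", "totalRaw", "cluster")
    if (!all(need %in% colnames(S4Vectors::mcols(object@ranges))))
        msg <- c(msg, paste("ranges must carry mcols:",
                            paste(need, collapse = ", ")))
    if (nrow(object@kmerFractions) && nrow(object@kmerFractions) != n)
        msg <- c(msg, "'kmerFractions' must be empty or have one row per region")
    if (nrow(object@kmerFractions)) {
        s <- rowSums(object@kmerFractions)
        if (any(abs(s - 1) > 1e-9))
            msg <- c(msg, "k-mer fractions must sum to 1 per region")
    }
    if (length(msg)) msg else TRUE
})

#' A fitted multivalency class model
#'
#' The result of clustering GeRM regions by their k-mer contribution
#' profiles: a 4-dimensional nonlinear embedding, an OPTICS reachability
#' profile, the knee-derived flat-cut threshold, per-region cluster labels
#' (noise = -1) and, once derived, the representative k-mers per cluster.
#'
#' @slot labels integer cluster label per region (-1 = noise), clusters
#'   numbered 1..K by decreasing size.
#' @slot embedding numeric matrix (regions x dims).
#' @slot reachability OPTICS reachability distances, in visit order.
#' @slot order OPTICS visit order (indices into the region set).
#' @slot threshold the flat-cut reachability threshold (knee rule).
#' @slot representativeKmers named list: cluster -> ordered k-mer vector.
#' @slot params list of the clustering parameters used.
#' @export
setClass("MultivalencyClasses",
    representation(labels = "integer", embedding = "matrix",
                   reachability = "numeric", order = "integer",
                   threshold = "numeric", representativeKmers = "list",
                   params = "list"))
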