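#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

# Integer-encode a nucleotide sequence: A=0 C=1 G=2 T=3, N=4.
# U is treated as T; any other letter is a hard error.
.encodeSeq <- function(sequence) {
    if (is(sequence, "XString")) sequence <- as.character(sequence)
    s <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "", fixed = TRUE)[[1]]
    enc <- match(s, c(.BASES, "N")) - 1L
    if (anyNA(enc))
        stop("invalid sequence alphabet: ",
             paste(unique(s[is.na(enc)]), collapse = ", "),
             " (allowed: A, C, G, T, U, N)")
    enc
}

#' Raw GeRM scores for a single sequence
#'
#' Computes the raw Generalized RNA Multivalency score for every k-mer start
#' position of a sequence. The score of the k-mer `A0` at position `p` is
#'
#' \deqn{g(p) = \sum_{k \le |i| \le w} e^{-\lambda\, d(A_0, A_{p+i})}\, \mathrm{weight}(i)}
#'
#' where `d` is the Hamming distance, `w = (n + 1) / 2`, and the weight
#' decays linearly from 1 at the centre to 0 at `|i| = w`. Neighbour k-mers
#' overlapping the centre (`|i| < k`) are ignored, positions outside the
#' sequence contribute 0, and k-mers containing N neither score nor
#' contribute as neighbours.
#'
#' @param sequence a character string or [Biostrings::DNAString] /
#'   [Biostrings::RNAString]; alphabet must be within A, C, G, T, U, N.
#' @param params a [GermParams] object.
#' @param weightScheme `"symmetric"` (default) uses `(w - |i|) / w`;
#'   `"literal"` uses the asymmetric `|w - i| / w` form, retained for
#'   comparison only.
#' @return numeric vector of length `L - k + 1` (empty when `L < k`),
#'   indexed by 0-based k-mer start position.
#' @examples
#' g <- germScore(strrep("GA", 100))
#' which.max(g)
#' @export
germScore <- function(sequence, params = GermParams(),
                      weightScheme = c("symmetric", "literal")) {
    stopifnot(is(params, "GermParams"))
    weightScheme <- match.arg(weightScheme)
    enc <- .encodeSeq(sequence)
    if (length(enc) < params@k) return(numeric(0))
    .germ_score_cpp(enc, params@k, germWindow(params), params@lambda,
                    if (weightScheme == "symmetric") 0L else 1L)
}

#' Score a set of transcripts
#'
#' Runs [germScore()] on every spliced transcript sequence of a
#' [TranscriptModels] object (or any named character vector / DNAStringSet)
#' and collects the raw tracks.
#'
#' @param x a [TranscriptModels], named [Biostrings::DNAStringSet] or named
#'   character vector.
#' @inheritParams germScore
#' @return a [GermTracks] with raw scores only; see [normalizeTracks()] and
#'   [smoothTracks()].
#' @export
scoreTranscripts <- function(x, params = GermParams(),
                             weightScheme = c("symmetric", "literal")) {
    weightScheme <- match.arg(weightScheme)
    seqs <- if (is(x, "TranscriptModels")) as.character(splicedSeqs(x))
            else if (is(x, "DNAStringSet")) as.character(x)
            else x
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("transcript sequences must carry unique names")
    raw <- lapply(seqs, germScore, params = params,
                  weightScheme = weightScheme)
    new("GermTracks", txId = names(seqs), raw = unname(raw),
        normalized = list(), smoothed = list(), params = params,
        stats = NULL)
}

#' Fit transcriptome normalization statistics
#'
#' Pools all raw scores of the supplied tracks and records their minimum and
#' median, so that [applyNormalization()] maps the pooled minimum to 0 and
#' the pooled median to 1.
#'
#' @param tracks a [GermTracks] with raw scores.
#' @param provenance free-text identifier of the transcript set.
#' @return a [NormalizationStats].
#' @export
fitNormalization <- function(tracks, provenance = "unspecified") {
    stopifnot(is(tracks, "GermTracks"))
    pooled <- unlist(tracks@raw, use.names = FALSE)
    if (length(unique(pooled)) < 2L)
        stop("degenerate raw score distribution: need at least two distinct values")
    m <- min(pooled)
    med <- median(pooled)
    if (med <= m)
        stop("degenerate raw score distribution: pooled median equals pooled minimum")
    new("NormalizationStats", minRaw = m, medianRaw = med,
        provenance = provenance)
}

#' Apply normalization statistics
#'
#' Affine rescaling `(x - min) / (median - min)`. Values from transcripts
#' outside the fitting set may fall below 0 or far above 1; no clipping is
#' performed.
#'
#' @param x a numeric vector or a [GermTracks].
#' @param stats a [NormalizationStats].
#' @return object of the same shape with normalized values (for
#'   `GermTracks`, the `normalized` slot is filled and `stats` recorded).
#' @export
applyNormalization <- function(x, stats) {
    stopifnot(is(stats, "NormalizationStats"))
    f <- function(v) (v - stats@minRaw) / (stats@medianRaw - stats@minRaw)
    if (is(x, "GermTracks")) {
        x@normalized <- lapply(x@raw, f)
        x@stats <- stats
        x
    } else f(x)
}

#' @rdname applyNormalization
#' @param tracks a [GermTracks] with raw scores.
#' @param provenance passed to [fitNormalization()].
#' @export
normalizeTracks <- function(tracks, stats = NULL,
                            provenance = "unspecified") {
    if (is.null(stats)) stats <- fitNormalization(tracks, provenance)
    applyNormalization(tracks, stats)
}

#' Centred moving-average smoothing
#'
#' Mean over a centred sliding window. At the edges the window is truncated
#' to in-bounds values (the mean is over however many positions fall inside
#' the track), so a constant track stays exactly constant.
#'
#' @param values numeric vector.
#' @param smoothWidth odd window width.
#' @return numeric vector of the same length.
#' @export
smoothTrack <- function(values, smoothWidth = 123L) {
    stopifnot(smoothWidth %% 2L == 1L)
    L <- length(values)
    if (L == 0L) return(numeric(0))
    half <- (smoothWidth - 1L) %/% 2L
    cs <- cumsum(c(0, values))
    idx <- seq_len(L)
    lo <- pmax(idx - half, 1L)
    hi <- pmin(idx + half, L)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth the tracks of a GermTracks object
#'
#' Applies [smoothTrack()] with the `smoothWidth` of the scoring parameters
#' to the normalized tracks (or the raw tracks when normalization has not
#' been run).
#'
#' @param tracks a [GermTracks].
#' @param on `"normalized"` (default, falls back to raw with a message) or
#'   `"raw"`.
#' @return the [GermTracks] with the `smoothed` slot filled.
#' @export
smoothTracks <- function(tracks, on = c("normalized", "raw")) {
    stopifnot(is(tracks, "GermTracks"))
    on <- match.arg(on)
    src <- if (on == "normalized" && length(tracks@normalized)) {
        tracks@normalized
    } else {
        if (on == "normalized")
            message("tracks not normalized yet; smoothing raw scores")
        tracks@raw
    }
    tracks@smoothed <- lapply(src, smoothTrack,
                              smoothWidth = tracks@params@smoothWidth)
    tracks
}

#' Score, normalize and smooth in one call
#'
#' Convenience pipeline: [scoreTranscripts()] then [normalizeTracks()]
#' (fitting the statistics on the supplied set) then [smoothTracks()].
#'
#' @inheritParams scoreTranscripts
#' @param provenance identifier recorded with the normalization statistics.
#' @return a fully populated [GermTracks].
#' @export
germTracks <- function(x, params = GermParams(),
                       weightScheme = c("symmetric", "literal"),
                       provenance = "supplied set") {
    tr <- scoreTranscripts(x, params, match.arg(weightScheme))
    tr <- normalizeTracks(tr, provenance = provenance)
    smoothTracks(tr)
}

#' Per-nucleotide view of a k-mer-indexed track
#'
#' Scores are anchored at k-mer start positions. For displays and per-base
#' statistics each nucleotide takes the score of the k-mer starting at it;
#' the trailing `k - 1` positions, where no k-mer starts, carry the last
#' defined value forward.
#'
#' @param values k-mer-indexed numeric vector (length `L - k + 1`).
#' @param k k-mer length.
#' @return numeric vector of length `L`.
#' @export
perNucleotide <- function(values, k = 5L) {
    if (!length(values)) return(numeric(0))
    c(values, rep(values[length(values)], k - 1L))
}
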