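#' @include AllClasses.R
NULL

# kmer-start positions (0-based) whose k-mer lies fully inside the CDS
.cdsKmerStarts <- function(cs, ce, k, L) {
    last <- min(ce - k, L - k)
    if (cs > last) return(integer(0))
    seq.int(cs, last)
}

# merge intervals (0-based half-open, two-column matrix) whose pairwise
# overlap is at least minOverlap nt; repeated to a fixpoint so the result is
# idempotent and independent of input order
.mergeByOverlap <- function(iv, minOverlap) {
    repeat {
        if (nrow(iv) < 2L) return(iv)
        iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
        merged <- iv[1L, , drop = FALSE]
        changed <- FALSE
        for (i in 2L:nrow(iv)) {
            last <- nrow(merged)
            ov <- min(merged[last, 2L], iv[i, 2L]) - max(merged[last, 1L], iv[i, 1L])
            if (ov >= minOverlap) {
                merged[last, 1L] <- min(merged[last, 1L], iv[i, 1L])
                merged[last, 2L] <- max(merged[last, 2L], iv[i, 2L])
                changed <- TRUE
            } else {
                merged <- rbind(merged, iv[i, , drop = FALSE])
            }
        }
        iv <- merged
        if (!changed) return(iv)
    }
}

#' Call high-multivalency CDS regions
#'
#' Pools the smoothed GeRM scores over all CDS k-mer positions of the
#' supplied transcript set and takes the stated percentile (linear
#' interpolation) as the calling threshold. Contiguous super-threshold runs
#' of CDS positions are extended by half the smoothing window on each side
#' (so a region contains every k-mer that fed its smoothed values), clipped
#' to the transcript; regions overlapping by at least `mergeOverlap`
#' nucleotides are merged; regions with at least `utrMaxFraction` of their
#' (post-extension) length inside an untranslated region are removed.
#'
#' @param tracks a smoothed [GermTracks] (see [germTracks()]).
#' @param models the matching [TranscriptModels].
#' @param percentile calling percentile of the pooled CDS smoothed scores
#'   (default 98).
#' @param mergeOverlap minimum overlap in nt for merging (default 41).
#' @param utrMaxFraction regions with at least this fraction of their
#'   length in UTR are excluded (default 1/3).
#' @param perTranscript compute the threshold per transcript instead of
#'   pooled over the set (default FALSE, the documented behaviour).
#' @return a [GermRegions] with per-region k-mer contribution fractions.
#' @export
callGermRegions <- function(tracks, models, percentile = 98,
                            mergeOverlap = 41L, utrMaxFraction = 1 / 3,
                            perTranscript = FALSE) {
    stopifnot(is(tracks, "GermTracks"), is(models, "TranscriptModels"))
    if (!length(tracks@smoothed))
        stop("tracks must be smoothed first; see smoothTracks()")
    ids <- tracks@txId
    if (!all(ids %in% txId(models)))
        stop("tracks contain transcripts absent from the models")
    models <- models[ids]
    k <- tracks@params@k
    half <- (tracks@params@smoothWidth - 1L) %/% 2L
    L <- Biostrings::width(splicedSeqs(models))
    cs <- cdsStart(models); ce <- cdsEnd(models)

    cdsIdx <- lapply(seq_along(ids), function(i)
        .cdsKmerStarts(cs[i], ce[i], k, L[i]))
    pooled <- unlist(lapply(seq_along(ids), function(i)
        tracks@smoothed[[i]][cdsIdx[[i]] + 1L]), use.names = FALSE)
    if (!length(pooled)) stop("no CDS k-mer positions in the supplied set")
    thr <- if (perTranscript) NULL
           else quantile(pooled, percentile / 100, names = FALSE, type = 7)

    seqs <- as.character(splicedSeqs(models))
    res <- list()
    for (i in seq_along(ids)) {
        idx <- cdsIdx[[i]]
        if (!length(idx)) next
        sm <- tracks@smoothed[[i]]
        t_i <- if (perTranscript)
            quantile(sm[idx + 1L], percentile / 100, names = FALSE, type = 7)
        else thr
        above <- sm[idx + 1L] > t_i
        if (!any(above)) next
        r <- rle(above)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        runs <- cbind(idx[starts[r$values]], idx[ends[r$values]])
        # nt intervals, extended by half the smoothing window, clipped
        iv <- cbind(pmax(0L, runs[, 1L] - half),
                    pmin(L[i], runs[, 2L] + k + half))
        iv <- .mergeByOverlap(iv, mergeOverlap)
        # UTR filter on the post-extension region
        len <- iv[, 2L] - iv[, 1L]
        utr <- pmax(0L, cs[i] - iv[, 1L]) + pmax(0L, iv[, 2L] - ce[i])
        iv <- iv[utr / len < utrMaxFraction, , drop = FALSE]
        if (!nrow(iv)) next
        for (j in seq_len(nrow(iv))) {
            p0 <- iv[j, 1L]; p1 <- iv[j, 2L]
            ks <- seq.int(p0, min(p1 - k, L[i] - k))
            kmers <- substring(seqs[i], ks + 1L, ks + k)
            rawv <- tracks@raw[[i]][ks + 1L]
            ok <- !grepl("N", kmers, fixed = TRUE)
            tot <- sum(rawv[ok])
            if (tot <= 0)
                stop("degenerate region with zero total raw score: ",
                     ids[i], ":", p0, "-", p1)
            fr <- tapply(rawv[ok], kmers[ok], sum) / tot
            res[[length(res) + 1L]] <- list(
                tx = ids[i], start = p0, end = p1,
                meanSmoothed = mean(sm[ks + 1L]), totalRaw = tot,
                fractions = fr)
        }
    }
    .buildGermRegions(res)
}

.buildGermRegions <- function(res) {
    if (!length(res)) {
        gr <- GenomicRanges::GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            regionId = character(0), meanSmoothed = numeric(0),
            totalRaw = numeric(0), cluster = character(0))
        return(new("GermRegions", ranges = gr,
                   kmerFractions = matrix(numeric(0), 0, 0)))
    }
    allK <- sort(unique(unlist(lapply(res, function(r) names(r$fractions)))))
    kf <- matrix(0, nrow = length(res), ncol = length(allK),
                 dimnames = list(NULL, allK))
    for (j in seq_along(res))
        kf[j, names(res[[j]]$fractions)] <- res[[j]]$fractions
    gr <- GenomicRanges::GRanges(
        vapply(res, `[[`, "", "tx"),
        IRanges::IRanges(vapply(res, `[[`, 0L, "start") + 1L,
                         vapply(res, `[[`, 0L, "end")))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        regionId = sprintf("%s:%d-%d", vapply(res, `[[`, "", "tx"),
                           vapply(res, `[[`, 0L, "start"),
                           vapply(res, `[[`, 0L, "end")),
        meanSmoothed = vapply(res, `[[`, 0, "meanSmoothed"),
        totalRaw = vapply(res, `[[`, 0, "totalRaw"),
        cluster = rep(NA_character_, length(res)))
    new("GermRegions", ranges = gr, kmerFractions = kf)
}

#' K-mer contribution fractions of an interval
#'
#' For a transcript interval, the fraction of the summed raw GeRM score
#' carried by each distinct k-mer occurring in it (fractions sum to 1).
#' Invariant under any affine rescaling of the scores.
#'
#' @param sequence the transcript sequence (character).
#' @param raw raw score track of the transcript (k-mer indexed).
#' @param start,end 0-based half-open interval on the transcript.
#' @param k k-mer length.
#' @return named numeric vector of fractions.
#' @export
kmerContributionFractions <- function(sequence, raw, start, end, k = 5L) {
    L <- nchar(sequence)
    stopifnot(start >= 0, end <= L, end - start >= k)
    ks <- seq.int(start, min(end - k, L - k))
    kmers <- substring(sequence, ks + 1L, ks + k)
    ok <- !grepl("N", kmers, fixed = TRUE)
    v <- raw[ks + 1L]
    tot <- sum(v[ok])
    if (tot <= 0) stop("degenerate region: total raw score is zero")
    sort(tapply(v[ok], kmers[ok], sum) / tot, decreasing = TRUE)
}
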