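#' @include AllClasses.R
NULL

#' Accessors for germkit classes
#'
#' Small generics exposing the slots of the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @param i subscript.
#' @param ... ignored.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("germWindow", function(x) standardGeneric("germWindow"))
#' @rdname accessors
#' @export
setMethod("germWindow", "GermParams", function(x) (x@n + 1L) %/% 2L)

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setMethod("kmerLength", "GermParams", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("txId", function(x) standardGeneric("txId"))
#' @rdname accessors
#' @export
setGeneric("geneId", function(x) standardGeneric("geneId"))
#' @rdname accessors
#' @export
setGeneric("cdsStart", function(x) standardGeneric("cdsStart"))
#' @rdname accessors
#' @export
setGeneric("cdsEnd", function(x) standardGeneric("cdsEnd"))
#' @rdname accessors
#' @export
setGeneric("exonLengths", function(x) standardGeneric("exonLengths"))
#' @rdname accessors
#' @export
setGeneric("splicedSeqs", function(x) standardGeneric("splicedSeqs"))
#' @rdname accessors
#' @export
setGeneric("isSpliced", function(x) standardGeneric("isSpliced"))
#' @rdname accessors
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))

#' @rdname accessors
#' @export
setMethod("txId", "TranscriptModels", function(x) names(x@seqs))
#' @rdname accessors
#' @export
setMethod("geneId", "TranscriptModels", function(x) x@geneId)
#' @rdname accessors
#' @export
setMethod("cdsStart", "TranscriptModels", function(x) x@cdsStart)
#' @rdname accessors
#' @export
setMethod("cdsEnd", "TranscriptModels", function(x) x@cdsEnd)
#' @rdname accessors
#' @export
setMethod("exonLengths", "TranscriptModels", function(x) x@exonLengths)
#' @rdname accessors
#' @export
setMethod("splicedSeqs", "TranscriptModels", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("isSpliced", "TranscriptModels", function(x) x@spliced)

#' @rdname accessors
#' @export
setMethod("cdsSeqs", "TranscriptModels", function(x) {
    Biostrings::subseq(x@seqs, start = x@cdsStart + 1L, end = x@cdsEnd)
})

#' @rdname accessors
#' @export
setMethod("length", "TranscriptModels", function(x) length(x@seqs))

#' @rdname accessors
#' @export
setMethod("[", "TranscriptModels", function(x, i, ...) {
    if (is.character(i)) i <- match(i, names(x@seqs))
    new("TranscriptModels", seqs = x@seqs[i], geneId = x@geneId[i],
        exonLengths = x@exonLengths[i], cdsStart = x@cdsStart[i],
        cdsEnd = x@cdsEnd[i], spliced = x@spliced[i])
})

setMethod("show", "TranscriptModels", function(object) {
    cat("TranscriptModels with", length(object), "transcripts,",
        length(unique(object@geneId)), "genes\n")
    if (length(object)) {
        L <- Biostrings::width(object@seqs)
        cat("  transcript length:", min(L), "-", max(L), "nt;",
            sum(object@spliced), "spliced\n")
    }
})

setMethod("show", "GermParams", function(object) {
    cat(sprintf("GermParams: k=%d, n=%d (w=%d), lambda=%g, smoothWidth=%d\n",
                object@k, object@n, germWindow(object), object@lambda,
                object@smoothWidth))
})

#' @rdname accessors
#' @export
setGeneric("rawScores", function(x) standardGeneric("rawScores"))
#' @rdname accessors
#' @export
setGeneric("normalizedScores", function(x) standardGeneric("normalizedScores"))
#' @rdname accessors
#' @export
setGeneric("smoothedScores", function(x) standardGeneric("smoothedScores"))
#' @rdname accessors
#' @export
setGeneric("germParams", function(x) standardGeneric("germParams"))
#' @rdname accessors
#' @export
setGeneric("normalizationStats", function(x) standardGeneric("normalizationStats"))

#' @rdname accessors
#' @export
setMethod("txId", "GermTracks", function(x) x@txId)
#' @rdname accessors
#' @export
setMethod("rawScores", "GermTracks", function(x) setNames(x@raw, x@txId))
#' @rdname accessors
#' @export
setMethod("normalizedScores", "GermTracks",
          function(x) setNames(x@normalized, x@txId))
#' @rdname accessors
#' @export
setMethod("smoothedScores", "GermTracks",
          function(x) setNames(x@smoothed, x@txId))
#' @rdname accessors
#' @export
setMethod("germParams", "GermTracks", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("normalizationStats", "GermTracks", function(x) x@stats)
#' @rdname accessors
#' @export
setMethod("length", "GermTracks", function(x) length(x@txId))

setMethod("show", "GermTracks", function(object) {
    cat("GermTracks over", length(object), "transcripts",
        if (length(object@normalized)) "(normalized" else "(raw only",
        if (length(object@smoothed)) "+ smoothed)" else ")", "\n")
    show(object@params)
})

setMethod("show", "NormalizationStats", function(object) {
    cat(sprintf("NormalizationStats: min=%g, median=%g [%s]\n",
                object@minRaw, object@medianRaw, object@provenance))
})

#' @rdname accessors
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))
#' @rdname accessors
#' @export
setGeneric("kmerFractions", function(x) standardGeneric("kmerFractions"))
#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname accessors
#' @export
setGeneric("representativeKmerSets",
           function(x) standardGeneric("representativeKmerSets"))

#' @rdname accessors
#' @export
setMethod("regionRanges", "GermRegions", function(x) x@ranges)
#' @rdname accessors
#' @export
setMethod("kmerFractions", "GermRegions", function(x) x@kmerFractions)
#' @rdname accessors
#' @export
setMethod("clusterLabels", "GermRegions",
          function(x) S4Vectors::mcols(x@ranges)$cluster)
#' @rdname accessors
#' @export
setMethod("length", "GermRegions", function(x) length(x@ranges))

#' @rdname accessors
#' @export
setMethod("[", "GermRegions", function(x, i, ...) {
    kf <- x@kmerFractions
    if (nrow(kf)) kf <- kf[i, , drop = FALSE]
    new("GermRegions", ranges = x@ranges[i], kmerFractions = kf)
})

setMethod("show", "GermRegions", function(object) {
    cat("GermRegions:", length(object), "regions on",
        length(unique(as.character(GenomicRanges::seqnames(object@ranges)))),
        "transcripts\n")
    cl <- clusterLabels(object)
    if (length(cl) && !all(is.na(cl)))
        cat("  clusters:", paste(names(table(cl)), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "MultivalencyClasses", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("representativeKmerSets", "MultivalencyClasses",
          function(x) x@representativeKmers)

setMethod("show", "MultivalencyClasses", function(object) {
    k <- sort(unique(object@labels[object@labels > 0L]))
    cat("MultivalencyClasses:", length(k), "clusters over",
        length(object@labels), "regions (",
        sum(object@labels == -1L), "noise )\n")
    cat(sprintf("  reachability threshold: %.4g\n", object@threshold))
})
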