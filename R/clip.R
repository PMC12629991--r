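#' @include clusters.R
NULL

#' Motif z-scores from RBNS enrichment tables
#'
#' Converts per-k-mer enrichment (R) scores to z-scores using the table's
#' own mean and standard deviation, computes one-sided upper-tail normal
#' p-values, and flags the significant set at `p < 0.05` (boundary
#' excluded).
#'
#' @param motifs data frame with columns `kmer` and `rScore` (optionally
#'   `rbp`), or a named numeric vector of R scores.
#' @return data frame with `z`, `p` and `significant` columns appended.
#' @export
motifZscores <- function(motifs) {
    if (is.numeric(motifs))
        motifs <- data.frame(kmer = names(motifs), rScore = unname(motifs))
    stopifnot(all(c("kmer", "rScore") %in% names(motifs)))
    if (length(unique(motifs$rScore)) < 2L)
        stop("need at least 2 distinct R scores")
    s <- sd(motifs$rScore)
    if (s == 0) stop("zero variance in R scores")
    motifs$z <- (motifs$rScore - mean(motifs$rScore)) / s
    motifs$p <- pnorm(motifs$z, lower.tail = FALSE)
    motifs$significant <- motifs$p < 0.05
    motifs
}

#' RBP binding potential of a sequence
#'
#' Rolling 5-mer decomposition of the sequence; the count of each
#' significant motif is multiplied by its z-score and the products summed
#' into a single score. Exactly reproducible (integer counts times fixed
#' z-scores).
#'
#' @param sequences character vector (e.g. CDSs).
#' @param motifTable output of [motifZscores()] for one RBP.
#' @return numeric vector, one score per sequence.
#' @export
bindingPotential <- function(sequences, motifTable) {
    stopifnot(all(c("kmer", "z", "significant") %in% names(motifTable)))
    sig <- motifTable[motifTable$significant, ]
    zmap <- setNames(sig$z, toupper(chartr("Uu", "Tt", sig$kmer)))
    k <- unique(nchar(names(zmap)))
    if (length(k) == 0L) k <- 5L
    stopifnot(length(k) == 1L)
    vapply(sequences, function(s) {
        s <- toupper(chartr("Uu", "Tt", s))
        L <- nchar(s)
        if (L < k) return(0)
        km <- substring(s, 1:(L - k + 1L), k:L)
        hit <- zmap[km]
        sum(hit, na.rm = TRUE)
    }, 0, USE.NAMES = !is.null(names(sequences)))
}

#' Within-k-mer percentiles of raw GeRM scores
#'
#' For every CDS k-mer instance in the supplied set, the percentile of its
#' raw GeRM score within the distribution of the *same* k-mer's scores
#' across the whole set (`100 * (rank - 0.5) / n`, so a k-mer with a single
#' instance sits at 50 by convention). High percentile = this occurrence of
#' the motif sits in an unusually multivalent context for that motif.
#'
#' @param models a [TranscriptModels].
#' @param tracks the matching raw [GermTracks].
#' @return data frame: `txId`, `pos` (0-based CDS k-mer start in transcript
#'   coordinates), `kmer`, `raw`, `percentile`.
#' @export
kmerGermPercentiles <- function(models, tracks) {
    inst <- .cdsKmerInstances(models, tracks)
    pct <- unlist(lapply(split(inst$raw, inst$kmer), function(v)
        100 * (rank(v, ties.method = "average") - 0.5) / length(v)),
        use.names = FALSE)
    inst$percentile <- pct[order(order(inst$kmer))]
    inst
}

#' Quality filtering of CLIP samples
#'
#' Two sequential filters mirroring standard CLIP QC: samples in the bottom
#' third by the proportion of crosslinks falling in CDS are excluded, then
#' samples in the bottom third of the remainder by raw CDS crosslink count
#' are excluded. Samples with zero CDS crosslinks are always excluded
#' (logged).
#'
#' @param crosslinks long data frame (`txId`, `pos`, `count`, `sampleId`).
#' @param models a [TranscriptModels].
#' @return the filtered crosslink data frame; kept sample ids in
#'   `attr(, "samples")`.
#' @export
filterClipSamples <- function(crosslinks, models) {
    cs <- setNames(cdsStart(models), txId(models))
    ce <- setNames(cdsEnd(models), txId(models))
    inCds <- crosslinks$pos >= cs[crosslinks$txId] &
             crosslinks$pos < ce[crosslinks$txId]
    tot <- tapply(crosslinks$count, crosslinks$sampleId, sum)
    cdsC <- tapply(crosslinks$count[inCds], crosslinks$sampleId[inCds], sum)
    samples <- names(tot)
    cdsC <- ifelse(is.na(cdsC[samples]), 0, cdsC[samples])
    zero <- samples[cdsC == 0]
    if (length(zero))
        message(length(zero), " sample(s) with zero CDS crosslinks excluded")
    samples <- setdiff(samples, zero)
    prop <- cdsC[samples] / tot[samples]
    drop1 <- samples[rank(prop, ties.method = "first") <=
                     floor(length(samples) / 3)]
    samples <- setdiff(samples, drop1)
    drop2 <- samples[rank(cdsC[samples], ties.method = "first") <=
                     floor(length(samples) / 3)]
    samples <- setdiff(samples, drop2)
    out <- crosslinks[crosslinks$sampleId %in% samples, , drop = FALSE]
    attr(out, "samples") <- samples
    out
}

#' Crosslink multivalency preference of a CLIP sample
#'
#' Each crosslinked nucleotide is mapped to the (at most five) CDS k-mers
#' covering it; every covered k-mer instance receives the crosslink's
#' count. Per k-mer, the crosslink-weighted mean of the instance
#' percentiles (see [kmerGermPercentiles()]) summarizes how multivalent the
#' contexts are in which that motif is crosslinked. The preference ratio
#' compares the mean of these per-k-mer values over the 50 most crosslinked
#' k-mers (ties broken lexicographically) with the mean over all other
#' crosslinked k-mers; a ratio of at least `passThreshold` (default 1.1)
#' marks a multivalency-preferring sample.
#'
#' @param crosslinks long data frame (`txId`, `pos`, `count`, `sampleId`),
#'   ideally after [filterClipSamples()].
#' @param models a [TranscriptModels].
#' @param tracks the matching raw [GermTracks].
#' @param top number of top crosslinked k-mers (default 50).
#' @param mapping `"overlapping"` (default: all k-mers covering the
#'   crosslink) or `"start"` (only the k-mer starting at it).
#' @param passThreshold ratio required to pass (default 1.1).
#' @param percentiles optionally a precomputed [kmerGermPercentiles()]
#'   table, to avoid recomputation across samples.
#' @return data frame, one row per sample: `sampleId`, `ratio`, `passes`,
#'   `nKmers` (crosslinked k-mers seen).
#' @export
clipMultivalencyPreference <- function(crosslinks, models, tracks,
                                       top = 50L,
                                       mapping = c("overlapping", "start"),
                                       passThreshold = 1.1,
                                       percentiles = NULL) {
    mapping <- match.arg(mapping)
    k <- tracks@params@k
    if (is.null(percentiles))
        percentiles <- kmerGermPercentiles(models, tracks)
    key <- paste(percentiles$txId, percentiles$pos)
    out <- list()
    for (smp in unique(crosslinks$sampleId)) {
        xl <- crosslinks[crosslinks$sampleId == smp & crosslinks$count > 0, ]
        offs <- if (mapping == "overlapping") (-(k - 1L)):0L else 0L
        # candidate k-mer starts covering each crosslink
        cand <- data.frame(
            txId = rep(xl$txId, each = length(offs)),
            pos = rep(xl$pos, each = length(offs)) + offs,
            count = rep(xl$count, each = length(offs)))
        hit <- match(paste(cand$txId, cand$pos), key)
        ok <- !is.na(hit)
        cand <- cand[ok, ]; hit <- hit[ok]
        if (!nrow(cand)) {
            out[[smp]] <- data.frame(sampleId = smp, ratio = NA_real_,
                                     passes = FALSE, nKmers = 0L)
            next
        }
        km <- percentiles$kmer[hit]
        pc <- percentiles$percentile[hit]
        wsum <- tapply(cand$count * pc, km, sum)
        wcnt <- tapply(cand$count, km, sum)
        meanPct <- wsum / wcnt
        ordk <- order(-wcnt, names(wcnt))
        topSet <- names(wcnt)[ordk][seq_len(min(top, length(wcnt)))]
        rest <- setdiff(names(meanPct), topSet)
        ratio <- if (length(rest)) mean(meanPct[topSet]) / mean(meanPct[rest])
                 else NA_real_
        out[[smp]] <- data.frame(sampleId = smp, ratio = ratio,
                                 passes = !is.na(ratio) &&
                                     ratio >= passThreshold,
                                 nKmers = length(wcnt))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Crosslink enrichment within GeRM regions
#'
#' For each region the crosslink density inside it is divided by the
#' density over the rest of that transcript's CDS; the mean of this ratio
#' per (sample, cluster) is the heatmap statistic. Transcripts in the
#' bottom half of CDS crosslink density (pooled over samples) are excluded
#' first. Regions whose rest-of-CDS has no crosslinks use `pseudocount` as
#' the denominator count (skip the region by setting `pseudocount = 0`).
#'
#' @param crosslinks long data frame (`txId`, `pos`, `count`, `sampleId`).
#' @param regions a [GermRegions] with cluster labels (see
#'   [clusterRegions()]); unclustered/noise regions are ignored.
#' @param models a [TranscriptModels].
#' @param pseudocount denominator count for empty rest-of-CDS (default
#'   0.5).
#' @param topHalfFilter apply the transcript density filter (default
#'   TRUE).
#' @return list with `byRegion` (per sample x region ratios) and `summary`
#'   (per sample x cluster mean ratio and region count).
#' @export
regionCrosslinkEnrichment <- function(crosslinks, regions, models,
                                      pseudocount = 0.5,
                                      topHalfFilter = TRUE) {
    gr <- regionRanges(regions)
    labels <- S4Vectors::mcols(gr)$cluster
    cs <- setNames(cdsStart(models), txId(models))
    ce <- setNames(cdsEnd(models), txId(models))
    inCds <- crosslinks$pos >= cs[crosslinks$txId] &
             crosslinks$pos < ce[crosslinks$txId]
    cdsXl <- crosslinks[inCds, , drop = FALSE]

    keepTx <- txId(models)
    if (topHalfFilter) {
        dens <- tapply(cdsXl$count, factor(cdsXl$txId, levels = keepTx), sum)
        dens <- ifelse(is.na(dens), 0, dens) / (ce[keepTx] - cs[keepTx])
        keepTx <- keepTx[rank(dens, ties.method = "first") >
                         length(dens) / 2]
    }
    rows <- list()
    for (smp in unique(cdsXl$sampleId)) {
        xl <- cdsXl[cdsXl$sampleId == smp, ]
        for (j in seq_along(gr)) {
            if (is.na(labels[j]) || labels[j] %in% c("-1", "noise")) next
            tx <- as.character(GenomicRanges::seqnames(gr))[j]
            if (!tx %in% keepTx) next
            r0 <- GenomicRanges::start(gr)[j] - 1L
            r1 <- GenomicRanges::end(gr)[j]
            # intersect region with CDS for the density bookkeeping
            a0 <- max(r0, cs[[tx]]); a1 <- min(r1, ce[[tx]])
            if (a1 <= a0) next
            inLen <- a1 - a0
            restLen <- (ce[[tx]] - cs[[tx]]) - inLen
            if (restLen <= 0) next
            txXl <- xl[xl$txId == tx, ]
            inC <- sum(txXl$count[txXl$pos >= a0 & txXl$pos < a1])
            restC <- sum(txXl$count) - inC
            if (restC == 0) {
                if (pseudocount <= 0) next
                restC <- pseudocount
            }
            rows[[length(rows) + 1L]] <- data.frame(
                sampleId = smp, regionId = S4Vectors::mcols(gr)$regionId[j],
                cluster = labels[j],
                ratio = (inC / inLen) / (restC / restLen))
        }
    }
    byRegion <- if (length(rows)) do.call(rbind, rows)
                else data.frame(sampleId = character(0),
                                regionId = character(0),
                                cluster = character(0), ratio = numeric(0))
    summary <- if (nrow(byRegion)) {
        agg <- aggregate(ratio ~ sampleId + cluster, byRegion, mean)
        agg$nRegions <- aggregate(ratio ~ sampleId + cluster, byRegion,
                                  length)$ratio
        names(agg)[names(agg) == "ratio"] <- "meanRatio"
        agg
    } else data.frame(sampleId = character(0), cluster = character(0),
                      meanRatio = numeric(0), nRegions = integer(0))
    list(byRegion = byRegion, summary = summary)
}

#' Crosslink metaprofile around region midpoints
#'
#' Sums crosslink counts at each position relative to the midpoints of the
#' supplied regions and normalizes by the number of regions and by the
#' sample's total crosslinks in millions, so profiles are comparable
#' across samples and region sets (doubling all counts leaves the profile
#' unchanged).
#'
#' @param crosslinks long data frame (`txId`, `pos`, `count`, `sampleId`).
#' @param regions a [GermRegions] (subset to one cluster for per-class
#'   profiles).
#' @param halfwidth window half-width in nt (default 500).
#' @return data frame: `sampleId`, `relPos` (-halfwidth..halfwidth),
#'   `value`.
#' @export
regionMetaprofile <- function(crosslinks, regions, halfwidth = 500L) {
    gr <- regionRanges(regions)
    mid <- floor((GenomicRanges::start(gr) - 1L + GenomicRanges::end(gr)) / 2)
    txs <- as.character(GenomicRanges::seqnames(gr))
    nReg <- length(gr)
    rel <- (-halfwidth):halfwidth
    out <- list()
    for (smp in unique(crosslinks$sampleId)) {
        xl <- crosslinks[crosslinks$sampleId == smp, ]
        totalM <- sum(xl$count) / 1e6
        prof <- numeric(length(rel))
        for (j in seq_len(nReg)) {
            txXl <- xl[xl$txId == txs[j], ]
            if (!nrow(txXl)) next
            d <- txXl$pos - mid[j]
            ok <- d >= -halfwidth & d <= halfwidth
            if (any(ok)) {
                idx <- d[ok] + halfwidth + 1L
                add <- vapply(split(txXl$count[ok], idx), sum, 0)
                prof[as.integer(names(add))] <-
                    prof[as.integer(names(add))] + add
            }
        }
        out[[smp]] <- data.frame(sampleId = smp, relPos = rel,
                                 value = prof / (nReg * totalM))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
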