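#' @include codon.R
NULL

#' Normalize conservation at synonymously mutable positions
#'
#' Per-base conservation scores (PhyloP-like, logarithmic scale) are
#' normalized in two subtractions so that codon identity and local baseline
#' drop out: each mutable position's value first has the conservation of
#' the middle base of its own codon subtracted (an internal per-instance
#' control — the middle base can never be synonymously mutated), and the
#' differences are then centred by their median within each
#' (codon, offset) type. A constant track therefore maps to exactly zero.
#'
#' @param records data frame of mutable-position records carrying `txId`,
#'   `pos` (0-based transcript coordinate of the mutable base), `offset`,
#'   `codon` and `ratio` (see [germCodonRatios()]; `pos` must be in
#'   transcript coordinates — add the CDS offset if the ratios were
#'   computed on the CDS).
#' @param cons named list of per-transcript conservation vectors (NA =
#'   missing). Records with missing conservation at the mutable or middle
#'   position are dropped and counted in a message.
#' @return the records with columns `conservation`, `middleConservation`
#'   and `normalizedConservation` appended.
#' @export
normalizeConservation <- function(records, cons) {
    stopifnot(all(c("txId", "pos", "offset", "codon") %in% names(records)))
    v <- mapply(function(tx, p) cons[[tx]][p + 1L],
                records$txId, records$pos)
    midPos <- records$pos - records$offset + 1L
    m <- mapply(function(tx, p) cons[[tx]][p + 1L],
                records$txId, midPos)
    keep <- !is.na(v) & !is.na(m)
    if (any(!keep))
        message(sum(!keep), " record(s) dropped for missing conservation")
    records <- records[keep, , drop = FALSE]
    v <- v[keep]; m <- m[keep]
    d <- v - m
    grp <- interaction(records$codon, records$offset, drop = TRUE)
    centred <- d - ave(d, grp, FUN = median)
    records$conservation <- v
    records$middleConservation <- m
    records$normalizedConservation <- centred
    records
}

#' Bin mutable positions by their codon-support ratio
#'
#' Equal-count binning by the GeRM codon ratio, performed separately within
#' each codon identity and then pooled, so every bin contains the same
#' proportion of each codon and codon-composition differences cannot drive
#' a bin trend.
#'
#' @param records output of [normalizeConservation()] (must carry `ratio`
#'   and `normalizedConservation`).
#' @param bins number of bins (default 10).
#' @return list with `records` (a `bin` column appended, 1 = lowest ratio)
#'   and `summary` (per-bin mean normalized conservation and count).
#' @export
binCodonRatios <- function(records, bins = 10L) {
    stopifnot("ratio" %in% names(records))
    records <- records[!is.na(records$ratio), , drop = FALSE]
    bin <- integer(nrow(records))
    for (cod in unique(records$codon)) {
        idx <- which(records$codon == cod)
        r <- rank(records$ratio[idx], ties.method = "first")
        bin[idx] <- ceiling(r / length(idx) * bins)
    }
    records$bin <- pmax(1L, bin)
    summ <- aggregate(normalizedConservation ~ bin, records, mean)
    summ$n <- as.vector(table(factor(records$bin, levels = summ$bin)))
    names(summ)[2L] <- "meanNormalizedConservation"
    list(records = records, summary = summ)
}
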