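#' @include core.R
NULL

.GC <- Biostrings::GENETIC_CODE

# split an in-frame CDS into codons (uppercase, T alphabet)
.codonsOf <- function(cds) {
    cds <- chartr("Uu", "Tt", toupper(cds))
    L <- nchar(cds)
    if (L %% 3L != 0L) stop("CDS length must be divisible by 3")
    substring(cds, seq(1L, L, 3L), seq(3L, L, 3L))
}

.aaOf <- function(codons) unname(.GC[codons])

#' Translate CDS sequences
#'
#' Thin wrapper over the standard genetic code; the terminal stop (if
#' present) is dropped. Internal stops are a hard error.
#'
#' @param cds character vector of in-frame CDS sequences.
#' @return character vector of protein sequences.
#' @export
translateCds <- function(cds) {
    vapply(cds, function(s) {
        aa <- .aaOf(.codonsOf(s))
        if (anyNA(aa)) stop("CDS contains non-ACGT codons")
        n <- length(aa)
        if (aa[n] == "*") aa <- aa[-n]
        if (any(aa == "*")) stop("internal stop codon in CDS")
        paste(aa, collapse = "")
    }, "", USE.NAMES = !is.null(names(cds)))
}

#' Synonymous codon shuffling
#'
#' Permutes codons among the positions of the same amino acid so that the
#' encoded protein is unchanged. With scope `"within_transcript"` each
#' transcript's per-amino-acid codon multiset is preserved exactly; with
#' `"transcriptome_wide"` the multiset is preserved over the pooled set and
#' redistributed across transcripts.
#'
#' @param cdsSet named character vector of in-frame CDS sequences.
#' @param scope `"within_transcript"` or `"transcriptome_wide"`.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the shuffle is reproducible.
#' @return named character vector of shuffled CDSs.
#' @export
shuffleCodons <- function(cdsSet,
                          scope = c("within_transcript", "transcriptome_wide"),
                          seed = NULL) {
    scope <- match.arg(scope)
    if (!is.null(seed)) set.seed(seed)
    codons <- lapply(cdsSet, .codonsOf)
    aas <- lapply(codons, function(cd) {
        aa <- .aaOf(cd)
        if (anyNA(aa)) stop("CDS contains non-ACGT codons")
        if (any(aa[-length(aa)] == "*")) stop("internal stop codon in CDS")
        aa
    })
    if (scope == "within_transcript") {
        shuffled <- mapply(function(cd, aa) {
            for (a in unique(aa)) {
                idx <- which(aa == a)
                cd[idx] <- cd[idx][sample.int(length(idx))]
            }
            paste(cd, collapse = "")
        }, codons, aas, SIMPLIFY = TRUE)
    } else {
        ntx <- lengths(codons)
        allCd <- unlist(codons, use.names = FALSE)
        allAa <- unlist(aas, use.names = FALSE)
        for (a in unique(allAa)) {
            idx <- which(allAa == a)
            allCd[idx] <- allCd[idx][sample.int(length(idx))]
        }
        ends <- cumsum(ntx)
        starts <- ends - ntx + 1L
        shuffled <- vapply(seq_along(codons), function(i)
            paste(allCd[starts[i]:ends[i]], collapse = ""), "")
    }
    setNames(shuffled, names(cdsSet))
}

#' Mean GeRM track over codon shuffles
#'
#' Element-wise mean of the raw GeRM tracks over `nShuffles` independent
#' synonymous shuffles — the null against which native multivalency is
#' compared.
#'
#' @inheritParams shuffleCodons
#' @param params a [GermParams].
#' @param nShuffles number of shuffles (default 10, the per-position
#'   convention; region-level analyses conventionally use 5).
#' @return named list of per-transcript mean raw score vectors.
#' @export
meanShuffledGerm <- function(cdsSet,
                             scope = c("within_transcript", "transcriptome_wide"),
                             nShuffles = 10L, params = GermParams(),
                             seed = NULL) {
    scope <- match.arg(scope)
    if (!is.null(seed)) set.seed(seed)
    acc <- NULL
    for (s in seq_len(nShuffles)) {
        sh <- shuffleCodons(cdsSet, scope)
        tr <- lapply(sh, germScore, params = params)
        acc <- if (is.null(acc)) tr
               else mapply(`+`, acc, tr, SIMPLIFY = FALSE)
    }
    lapply(acc, `/`, nShuffles)
}

# per-codon lookup of synonymously mutable positions, built once:
# list codon -> list(offset -> alternative bases)
.mutableTable <- local({
    tab <- NULL
    function() {
        if (!is.null(tab)) return(tab)
        t0 <- list()
        for (cod in names(.GC)) {
            aa <- .GC[[cod]]
            offs <- list()
            for (off in 0:2) {
                nat <- substr(cod, off + 1L, off + 1L)
                alts <- setdiff(.BASES, nat)
                syn <- alts[vapply(alts, function(b) {
                    mut <- cod
                    substr(mut, off + 1L, off + 1L) <- b
                    .GC[[mut]] == aa
                }, FALSE)]
                if (length(syn)) offs[[as.character(off)]] <- syn
            }
            t0[[cod]] <- offs
        }
        tab <<- t0
        tab
    }
})

#' Enumerate synonymously mutable positions of a CDS
#'
#' Every nucleotide position that admits at least one single-nucleotide
#' synonymous substitution under the standard genetic code: third positions
#' of degenerate codons plus the first positions of the four/six-fold
#' leucine (CTA/CTG <-> TTA/TTG) and arginine (CGA/CGG <-> AGA/AGG) codons.
#'
#' @param cds an in-frame CDS (character).
#' @return data frame with 0-based `codonIndex`, `offset` (position within
#'   the codon), `pos` (nucleotide position in the CDS), `codon`, `native`
#'   base and `alternatives` (comma-separated bases).
#' @export
mutablePositions <- function(cds) {
    codons <- .codonsOf(cds)
    tab <- .mutableTable()
    out <- list()
    for (i in seq_along(codons)) {
        cod <- codons[i]
        if (!cod %in% names(tab)) {
            message("codon ", i - 1L, " ('", cod, "') contains a non-ACGT base; skipped")
            next
        }
        offs <- tab[[cod]]
        for (off in names(offs)) {
            o <- as.integer(off)
            out[[length(out) + 1L]] <- data.frame(
                codonIndex = i - 1L, offset = o, pos = 3L * (i - 1L) + o,
                codon = cod, native = substr(cod, o + 1L, o + 1L),
                alternatives = paste(offs[[off]], collapse = ","))
        }
    }
    if (!length(out))
        return(data.frame(codonIndex = integer(0), offset = integer(0),
                          pos = integer(0), codon = character(0),
                          native = character(0), alternatives = character(0)))
    do.call(rbind, out)
}

# Exact local rescoring window around nucleotide ntPos: the <= k k-mers
# overlapping the position depend only on nucleotides within w + k - 1 of
# their starts, so scoring this context reproduces full-transcript scores
# exactly (context edges coincide with transcript edges whenever clipping
# occurs, so the edge rule agrees too).
.localMaxGerm <- function(enc, ntPos, params, mutateTo = NULL) {
    k <- params@k; w <- germWindow(params); L <- length(enc)
    c0 <- max(0L, ntPos - k + 1L - w)
    c1 <- min(L, ntPos + w + k)          # 0-based half-open
    ctx <- enc[(c0 + 1L):c1]
    if (!is.null(mutateTo)) ctx[ntPos - c0 + 1L] <- mutateTo
    sc <- .germ_score_cpp(ctx, k, w, params@lambda, 0L)
    s0 <- max(0L, ntPos - k + 1L)
    s1 <- min(L - k, ntPos)
    max(sc[(s0 - c0 + 1L):(s1 - c0 + 1L)])
}

#' GeRM codon-support ratios
#'
#' For each synonymously mutable position, the maximum raw GeRM score over
#' the k-mers overlapping the native base, divided by the mean of the same
#' maxima computed after each possible synonymous single-nucleotide
#' substitution. A ratio above 1 means the native codon choice supports the
#' local multivalency. Raw (unsmoothed, unnormalized) scores are used; the
#' edge rule of the score applies unchanged near transcript ends, so no
#' positions are excluded.
#'
#' @param cds an in-frame CDS (character).
#' @param params a [GermParams].
#' @param positions optionally a subset of [mutablePositions()] rows.
#' @return data frame with the columns of [mutablePositions()] plus
#'   `nativeMaxGerm`, `mutantMeanMaxGerm` and `ratio`.
#' @export
germCodonRatios <- function(cds, params = GermParams(), positions = NULL) {
    if (is.null(positions)) positions <- mutablePositions(cds)
    if (!nrow(positions)) return(cbind(positions, nativeMaxGerm = numeric(0),
                                       mutantMeanMaxGerm = numeric(0),
                                       ratio = numeric(0)))
    enc <- .encodeSeq(cds)
    baseCode <- setNames(0:3, .BASES)
    native <- numeric(nrow(positions))
    mutant <- numeric(nrow(positions))
    for (r in seq_len(nrow(positions))) {
        p <- positions$pos[r]
        native[r] <- .localMaxGerm(enc, p, params)
        alts <- strsplit(positions$alternatives[r], ",", fixed = TRUE)[[1]]
        mutant[r] <- mean(vapply(alts, function(b)
            .localMaxGerm(enc, p, params, mutateTo = baseCode[[b]]), 0))
    }
    out <- positions
    out$nativeMaxGerm <- native
    out$mutantMeanMaxGerm <- mutant
    bad <- mutant == 0
    out$ratio <- ifelse(bad, NA_real_, native / mutant)
    if (any(bad))
        message(sum(bad), " position(s) with zero mutant score dropped from ratios")
    out
}

# count of k-mers composed only of A and G
.countAGOnly <- function(isAG, k = 5L) {
    L <- length(isAG)
    if (L < k) return(0L)
    cs <- cumsum(c(0L, isAG))
    sum((cs[(k + 1L):(L + 1L)] - cs[1L:(L - k + 1L)]) == k)
}

#' Count purine-only (AG-only) k-mers
#'
#' The number of length-`k` windows of the sequence consisting solely of A
#' and G — the objective optimized by [recodeCds()].
#'
#' @param sequence character.
#' @param k window size (default 5).
#' @return integer count.
#' @export
countAGOnlyKmers <- function(sequence, k = 5L) {
    s <- strsplit(chartr("Uu", "Tt", toupper(sequence)), "")[[1]]
    .countAGOnly(s %in% c("A", "G"), k)
}

#' Synonymously recode a CDS towards or away from GA multivalency
#'
#' Greedy coordinate descent over codons: each sweep visits the codons in a
#' seeded random order and replaces a codon by the synonymous alternative
#' that best improves the count of AG-only 5-mers (ties broken by total A+G
#' content in the requested direction), subject to (i) the protein sequence
#' never changing, (ii) GC content staying within `gcTolerance` of the
#' input, and (iii) protected spans staying byte-identical. Sweeps repeat
#' until a local optimum under single-codon moves is reached; several
#' random-order restarts are taken and the best result returned.
#'
#' @param cds in-frame CDS (character).
#' @param objective `"minimize"` or `"maximize"` the AG-only 5-mer count.
#' @param gcTolerance allowed absolute deviation in GC fraction
#'   (default 0.02).
#' @param protectedSpans optional integer matrix / 2-column data frame of
#'   0-based half-open CDS intervals that must not change.
#' @param seed integer seed for the sweep orders.
#' @param nRestarts number of random restarts (default 4).
#' @return list with `cds` (the recoded sequence), `objective` (its AG-only
#'   5-mer count), `native` (the input count) and `gc` (the output GC
#'   fraction).
#' @export
recodeCds <- function(cds, objective = c("minimize", "maximize"),
                      gcTolerance = 0.02, protectedSpans = NULL,
                      seed = NULL, nRestarts = 4L) {
    objective <- match.arg(objective)
    if (!is.null(seed)) set.seed(seed)
    dirn <- if (objective == "minimize") -1L else 1L
    codons0 <- .codonsOf(cds)
    aa <- .aaOf(codons0)
    if (anyNA(aa)) stop("CDS contains non-ACGT codons")
    nC <- length(codons0)
    L <- 3L * nC
    gc0 <- sum(strsplit(cds, "")[[1]] %in% c("G", "C")) / L

    frozen <- rep(FALSE, nC)
    if (!is.null(protectedSpans)) {
        ps <- as.matrix(protectedSpans)
        for (r in seq_len(nrow(ps))) {
            lo <- ps[r, 1L] %/% 3L
            hi <- (ps[r, 2L] - 1L) %/% 3L
            frozen[(lo + 1L):(hi + 1L)] <- TRUE
        }
    }
    synTab <- lapply(aa, function(a) names(.GC)[.GC == a])
    gcOf <- vapply(names(.GC), function(cd)
        sum(strsplit(cd, "")[[1]] %in% c("G", "C")), 0L)
    agOf <- vapply(names(.GC), function(cd)
        sum(strsplit(cd, "")[[1]] %in% c("A", "G")), 0L)

    # For short sequences the GC tolerance can forbid every single-codon
    # step towards the optimum (one substitution already shifts GC by more
    # than the tolerance), so small search spaces are enumerated exactly.
    freeSyn <- synTab
    freeSyn[frozen] <- lapply(which(frozen), function(i) codons0[i])
    spaceSize <- prod(lengths(freeSyn))
    if (spaceSize <= 2e5) {
        grid <- expand.grid(freeSyn, stringsAsFactors = FALSE)
        best <- NULL
        for (r in seq_len(nrow(grid))) {
            cand <- as.character(grid[r, ])
            s <- strsplit(paste(cand, collapse = ""), "")[[1]]
            gcf <- sum(s %in% c("G", "C")) / L
            if (abs(gcf - gc0) > gcTolerance) next
            obj <- .countAGOnly(s %in% c("A", "G"))
            ag <- sum(s %in% c("A", "G"))
            better <- is.null(best) ||
                dirn * obj > dirn * best$obj ||
                (obj == best$obj && dirn * ag > dirn * best$ag) ||
                (obj == best$obj && ag == best$ag &&
                 paste(cand, collapse = "") < paste(best$codons, collapse = ""))
            if (better) best <- list(codons = cand, obj = obj, gc = gcf,
                                     ag = ag)
        }
        if (is.null(best))
            stop("no synonymous recoding satisfies the GC tolerance")
        out <- paste(best$codons, collapse = "")
        stopifnot(identical(translateCds(out), translateCds(cds)))
        return(list(cds = out, objective = best$obj,
                    native = countAGOnlyKmers(cds), gc = best$gc))
    }

    evalState <- function(codons) {
        s <- strsplit(paste(codons, collapse = ""), "")[[1]]
        list(isAG = s %in% c("A", "G"),
             obj = .countAGOnly(s %in% c("A", "G")),
             gcCount = sum(s %in% c("G", "C")))
    }

    runOnce <- function() {
        codons <- codons0
        st <- evalState(codons)
        isAG <- st$isAG; obj <- st$obj; gcCount <- st$gcCount
        repeat {
            improved <- FALSE
            for (i in sample.int(nC)) {
                if (frozen[i]) next
                cands <- setdiff(synTab[[i]], codons[i])
                if (!length(cands)) next
                lo <- max(1L, 3L * (i - 1L) + 1L - 4L)
                hi <- min(L - 4L, 3L * i)
                oldWin <- .countAGOnly(isAG[lo:(hi + 4L)])
                best <- NULL
                for (cand in cands) {
                    newGc <- gcCount - gcOf[[codons[i]]] + gcOf[[cand]]
                    if (abs(newGc / L - gc0) > gcTolerance) next
                    tmp <- isAG
                    tmp[(3L * (i - 1L) + 1L):(3L * i)] <-
                        strsplit(cand, "")[[1]] %in% c("A", "G")
                    dObj <- .countAGOnly(tmp[lo:(hi + 4L)]) - oldWin
                    dAG <- agOf[[cand]] - agOf[[codons[i]]]
                    key <- c(dirn * dObj, dirn * dAG)
                    if (key[1L] > 0 || (key[1L] == 0 && key[2L] > 0)) {
                        if (is.null(best) || key[1L] > best$key[1L] ||
                            (key[1L] == best$key[1L] && key[2L] > best$key[2L]))
                            best <- list(cand = cand, key = key, isAG = tmp,
                                         gc = newGc, dObj = dObj)
                    }
                }
                if (!is.null(best)) {
                    codons[i] <- best$cand
                    isAG <- best$isAG
                    gcCount <- best$gc
                    obj <- obj + best$dObj
                    improved <- TRUE
                }
            }
            if (!improved) break
        }
        list(codons = codons, obj = obj, gc = gcCount / L,
             ag = sum(isAG))
    }

    best <- NULL
    for (r in seq_len(nRestarts)) {
        cur <- runOnce()
        better <- is.null(best) ||
            dirn * cur$obj > dirn * best$obj ||
            (cur$obj == best$obj && dirn * cur$ag > dirn * best$ag)
        if (better) best <- cur
    }
    out <- paste(best$codons, collapse = "")
    stopifnot(identical(translateCds(out), translateCds(cds)))
    stopifnot(abs(best$gc - gc0) <= gcTolerance + 1e-12)
    if (!is.null(protectedSpans)) {
        ps <- as.matrix(protectedSpans)
        for (r in seq_len(nrow(ps)))
            stopifnot(identical(substr(out, ps[r, 1L] + 1L, ps[r, 2L]),
                                substr(cds, ps[r, 1L] + 1L, ps[r, 2L])))
    }
    list(cds = out, objective = best$obj,
         native = countAGOnlyKmers(cds), gc = best$gc)
}
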