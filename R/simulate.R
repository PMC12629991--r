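#' @include codon.R
NULL

# human-like relative codon usage (per amino acid); static bundled table
.CODON_USAGE <- c(
    GCT = .27, GCC = .40, GCA = .23, GCG = .11,                       # A
    CGT = .08, CGC = .18, CGA = .11, CGG = .20, AGA = .21, AGG = .21, # R
    AAT = .47, AAC = .53, GAT = .46, GAC = .54,                       # N D
    TGT = .46, TGC = .54, CAA = .27, CAG = .73,                       # C Q
    GAA = .42, GAG = .58, GGT = .16, GGC = .34, GGA = .25, GGG = .25, # E G
    CAT = .42, CAC = .58, ATT = .36, ATC = .47, ATA = .17,            # H I
    TTA = .08, TTG = .13, CTT = .13, CTC = .20, CTA = .07, CTG = .40, # L
    AAA = .43, AAG = .57, ATG = 1.0, TTT = .46, TTC = .54,            # K M F
    CCT = .29, CCC = .32, CCA = .28, CCG = .11,                       # P
    TCT = .19, TCC = .22, TCA = .15, TCG = .05, AGT = .15, AGC = .24, # S
    ACT = .25, ACC = .36, ACA = .28, ACG = .11, TGG = 1.0,            # T W
    TAT = .44, TAC = .56, GTT = .18, GTC = .24, GTA = .12, GTG = .46, # Y V
    TAA = .30, TAG = .24, TGA = .46)                                  # *

# human-like amino-acid frequencies for background CDS
.AA_FREQ <- c(A = .070, R = .056, N = .036, D = .047, C = .023, Q = .047,
              E = .071, G = .066, H = .026, I = .043, L = .100, K = .057,
              M = .021, F = .037, P = .063, S = .083, T = .054, W = .012,
              Y = .027, V = .060)

# planted multivalency classes. Low-complexity domains are repetitive, so
# the planted amino-acid sequence tiles a class repeat unit (with a small
# substitution rate drawn from the class composition); the class-consistent
# ("preferred") codons then make the repeat multivalent at the RNA level.
# The GA class encodes an R/E/K-rich mixed-charge domain with AGA/AGG/CGA
# arginine bias; the GC class an R/A/P/G domain with CGG/CGC bias; CAG a
# glutamine repeat; C a C-rich P/S/T stretch.
.CLASS_DEFS <- list(
    GA = list(unit = c("R", "E", "R", "K"),
              aa = c(R = .35, E = .25, K = .20, S = .10, G = .05, D = .05),
              pref = list(R = c("AGA", "AGG", "CGA"), E = "GAA",
                          K = "AAG", S = "AGC", G = "GGA", D = "GAT")),
    CAG = list(unit = "Q",
               aa = c(Q = .80, A = .10, P = .10),
               pref = list(Q = "CAG", A = "GCA", P = "CCA")),
    GC = list(unit = c("G", "A", "R", "P"),
              aa = c(G = .30, A = .30, P = .20, R = .20),
              pref = list(G = "GGC", A = "GCC",
                          P = "CCG", R = c("CGG", "CGC"))),
    C = list(unit = c("P", "S", "P", "T"),
             aa = c(P = .40, S = .30, T = .20, L = .10),
             pref = list(P = "CCC", S = "TCC", T = "ACC", L = "CTC")))

.senseCodons <- function() names(.GC)[.GC != "*"]

.randomSeq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                collapse = "")

# codon-frequency-matched random coding sequence (no stops)
.backgroundCodons <- function(n) {
    aa <- sample(names(.AA_FREQ), n, replace = TRUE, prob = .AA_FREQ)
    vapply(aa, function(a) {
        cods <- names(.GC)[.GC == a]
        sample(cods, 1L, prob = .CODON_USAGE[cods])
    }, "")
}

# codons for a planted stretch of the given class: the amino-acid sequence
# tiles the class repeat unit (random phase, 10% substitutions from the
# class composition); with probability `bias` each codon is drawn from the
# class-preferred set, otherwise uniformly from all synonyms
.plantedCodons <- function(class, n, bias, unitFidelity = 0.9) {
    def <- .CLASS_DEFS[[class]]
    unit <- def$unit
    phase <- sample.int(length(unit), 1L)
    aa <- unit[(seq_len(n) + phase - 2L) %% length(unit) + 1L]
    sub <- runif(n) > unitFidelity
    if (any(sub))
        aa[sub] <- sample(names(def$aa), sum(sub), replace = TRUE,
                          prob = def$aa)
    vapply(aa, function(a) {
        if (runif(1) < bias) {
            p <- def$pref[[a]]
            if (length(p) == 1L) p else sample(p, 1L)
        } else {
            cods <- names(.GC)[.GC == a]
            if (length(cods) == 1L) cods else sample(cods, 1L)
        }
    }, "")
}

#' Simulation configuration
#'
#' Parameters of the synthetic transcriptome: number of genes, fraction
#' carrying a planted multivalent region, the planted classes (GA-rich
#' mixed-charge-domain coding, CAG repeat, GC-rich, C-rich), planted length
#' range, codon-bias strength (probability that a degenerate codon choice
#' follows the class-consistent bias), CDS/UTR/exon geometry. Exon counts
#' 3-12 with log-normal lengths (median ~150 nt) mirror typical spliced
#' mRNAs.
#'
#' @param nGenes number of genes (default 200).
#' @param plantedFraction fraction of genes with a planted region
#'   (default 0.1).
#' @param classes planted classes, cycled over planted genes.
#' @param plantedCodons codon-count range of the planted stretch
#'   (default 84-133, i.e. 252-399 nt).
#' @param codonBias bias strength in `[0, 1]` (default 0.9).
#' @param cdsCodons background CDS codon-count range.
#' @param utrLength UTR length range (nt, each side).
#' @param exonCount exon count range.
#' @param exonMeanLog,exonSdLog log-normal exon length parameters.
#' @param intronLength intron length range (nt).
#' @return a list of class `germSimConfig`.
#' @export
simulationConfig <- function(nGenes = 200L, plantedFraction = 0.1,
                             classes = c("GA", "CAG", "GC", "C"),
                             plantedCodons = c(84L, 133L), codonBias = 0.9,
                             cdsCodons = c(280L, 520L),
                             utrLength = c(100L, 300L),
                             exonCount = c(3L, 12L),
                             exonMeanLog = log(150), exonSdLog = 0.4,
                             intronLength = c(80L, 400L)) {
    stopifnot(plantedFraction >= 0, plantedFraction <= 1,
              codonBias >= 0, codonBias <= 1,
              all(classes %in% names(.CLASS_DEFS)))
    structure(list(nGenes = as.integer(nGenes),
                   plantedFraction = plantedFraction, classes = classes,
                   plantedCodons = as.integer(plantedCodons),
                   codonBias = codonBias, cdsCodons = as.integer(cdsCodons),
                   utrLength = as.integer(utrLength),
                   exonCount = as.integer(exonCount),
                   exonMeanLog = exonMeanLog, exonSdLog = exonSdLog,
                   intronLength = as.integer(intronLength)),
              class = "germSimConfig")
}

.splitLengths <- function(L, n, meanLog, sdLog) {
    w <- rlnorm(n, meanLog, sdLog)
    lens <- floor(w / sum(w) * L)
    lens[lens < 1L] <- 1L
    extra <- L - sum(lens)
    if (extra > 0) {
        add <- rep(extra %/% n, n)
        add[seq_len(extra %% n)] <- add[seq_len(extra %% n)] + 1L
        lens <- lens + add
    } else if (extra < 0) {
        i <- which.max(lens)
        lens[i] <- lens[i] + extra
    }
    as.integer(lens)
}

#' Simulate a transcriptome with planted multivalent regions
#'
#' Generates multi-exon spliced transcripts (half on the minus strand) with
#' codon-frequency-matched random CDSs; a configured fraction carry a
#' planted class-specific multivalent stretch encoding a low-complexity
#' domain. Emits an in-memory genome, annotation and [TranscriptModels]
#' plus a truth table, all deterministic under `seed`.
#'
#' @param config a [simulationConfig()].
#' @param seed integer seed.
#' @return list with `models` ([TranscriptModels]), `genome`
#'   ([Biostrings::DNAStringSet] of per-gene loci), `gtf` (annotation rows
#'   as a data frame), `truth` (per-transcript truth: class, bias, planted
#'   region in transcript coordinates) and the `config`/`seed` used.
#' @seealso [writeSimulation()] to emit FASTA/GTF/TSV files.
#' @export
simulateTranscriptome <- function(config = simulationConfig(), seed) {
    stopifnot(inherits(config, "germSimConfig"))
    set.seed(seed)
    n <- config$nGenes
    nPlanted <- round(n * config$plantedFraction)
    plantedIdx <- if (nPlanted > 0) sort(sample.int(n, nPlanted)) else integer(0)
    classOf <- setNames(rep(config$classes, length.out = nPlanted),
                        plantedIdx)

    txRows <- list(); gtfRows <- list(); chrSeqs <- character(n)
    chrNames <- sprintf("chr%04d", seq_len(n))
    for (i in seq_len(n)) {
        gid <- sprintf("G%04d", i); tid <- sprintf("T%04d", i)
        nCod <- sample(config$cdsCodons[1L]:config$cdsCodons[2L], 1L)
        bg <- .backgroundCodons(nCod)
        regionStartCds <- NA_integer_; regionEndCds <- NA_integer_
        cls <- NA_character_
        if (i %in% plantedIdx) {
            cls <- classOf[[as.character(i)]]
            pc <- sample(config$plantedCodons[1L]:config$plantedCodons[2L], 1L)
            at <- sample(10:(nCod - 10L), 1L)
            planted <- .plantedCodons(cls, pc, config$codonBias)
            bg <- c(bg[seq_len(at)], planted, bg[(at + 1L):nCod])
            # +1 codon for the ATG prepended below
            regionStartCds <- 3L * (at + 1L)
            regionEndCds <- regionStartCds + 3L * pc
        }
        stopCod <- sample(c("TAA", "TAG", "TGA"), 1L,
                          prob = .CODON_USAGE[c("TAA", "TAG", "TGA")])
        cds <- paste(c("ATG", bg, stopCod), collapse = "")
        u5 <- .randomSeq(sample(config$utrLength[1L]:config$utrLength[2L], 1L))
        u3 <- .randomSeq(sample(config$utrLength[1L]:config$utrLength[2L], 1L))
        txSeq <- paste0(u5, cds, u3)
        L <- nchar(txSeq)
        cdsStart <- nchar(u5); cdsEnd <- cdsStart + nchar(cds)

        nE <- sample(config$exonCount[1L]:config$exonCount[2L], 1L)
        exLens <- .splitLengths(L, nE, config$exonMeanLog, config$exonSdLog)
        intLens <- if (nE > 1L)
            sample(config$intronLength[1L]:config$intronLength[2L], nE - 1L,
                   replace = TRUE) else integer(0)
        strand <- sample(c("+", "-"), 1L)

        # assemble the plus-orientation locus: flank exon intron ... flank
        flank <- 50L
        pieces <- character(0)
        exStartPlus <- integer(nE)   # 1-based on the plus-orientation locus
        posCursor <- flank
        txOff <- cumsum(c(0L, exLens))[seq_len(nE)]
        for (e in seq_len(nE)) {
            exStartPlus[e] <- posCursor + 1L
            pieces <- c(pieces, substr(txSeq, txOff[e] + 1L,
                                       txOff[e] + exLens[e]))
            posCursor <- posCursor + exLens[e]
            if (e < nE) {
                pieces <- c(pieces, .randomSeq(intLens[e]))
                posCursor <- posCursor + intLens[e]
            }
        }
        locusPlus <- paste0(.randomSeq(flank), paste(pieces, collapse = ""),
                            .randomSeq(flank))
        Lc <- nchar(locusPlus)
        if (strand == "+") {
            chrSeqs[i] <- locusPlus
            exStart <- exStartPlus
            exEnd <- exStartPlus + exLens - 1L
        } else {
            chrSeqs[i] <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(locusPlus)))
            exEnd <- Lc - exStartPlus + 1L
            exStart <- exEnd - exLens + 1L
        }

        attrStr <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
        addRow <- function(feature, s, e, frame = ".") {
            gtfRows[[length(gtfRows) + 1L]] <<- data.frame(
                seqname = chrNames[i], source = "germkit_sim",
                feature = feature, start = s, end = e, score = ".",
                strand = strand, frame = frame, attributes = attrStr)
        }
        addRow("gene", min(exStart), max(exEnd))
        addRow("transcript", min(exStart), max(exEnd))
        for (e in seq_len(nE)) addRow("exon", exStart[e], exEnd[e])
        # CDS segments: intersect the CDS transcript interval with each exon
        phase <- 0L
        for (e in seq_len(nE)) {
            t0 <- max(txOff[e], cdsStart)
            t1 <- min(txOff[e] + exLens[e], cdsEnd)
            if (t1 <= t0) next
            if (strand == "+") {
                s <- exStart[e] + (t0 - txOff[e])
                addRow("CDS", s, s + (t1 - t0) - 1L, frame = phase)
            } else {
                e1 <- exEnd[e] - (t0 - txOff[e])
                addRow("CDS", e1 - (t1 - t0) + 1L, e1, frame = phase)
            }
            phase <- (3L - ((t1 - t0) - phase) %% 3L) %% 3L
        }
        txRows[[i]] <- list(tid = tid, gid = gid, seq = txSeq,
                            exonLengths = exLens, cdsStart = cdsStart,
                            cdsEnd = cdsEnd,
                            class = cls, regionStartCds = regionStartCds,
                            regionEndCds = regionEndCds)
    }

    seqs <- Biostrings::DNAStringSet(vapply(txRows, `[[`, "", "seq"))
    names(seqs) <- vapply(txRows, `[[`, "", "tid")
    models <- new("TranscriptModels", seqs = seqs,
                  geneId = vapply(txRows, `[[`, "", "gid"),
                  exonLengths = lapply(txRows, `[[`, "exonLengths"),
                  cdsStart = vapply(txRows, function(r) r$cdsStart, 0L),
                  cdsEnd = vapply(txRows, function(r) r$cdsEnd, 0L),
                  spliced = rep(TRUE, n))
    truth <- data.frame(
        txId = vapply(txRows, `[[`, "", "tid"),
        geneId = vapply(txRows, `[[`, "", "gid"),
        class = vapply(txRows, `[[`, "", "class"),
        bias = ifelse(is.na(vapply(txRows, `[[`, "", "class")), NA_real_,
                      config$codonBias),
        cdsStart = vapply(txRows, function(r) r$cdsStart, 0L),
        cdsEnd = vapply(txRows, function(r) r$cdsEnd, 0L),
        regionStart = vapply(txRows, function(r)
            r$cdsStart + r$regionStartCds, 0L),
        regionEnd = vapply(txRows, function(r)
            r$cdsStart + r$regionEndCds, 0L))
    genome <- Biostrings::DNAStringSet(chrSeqs)
    names(genome) <- chrNames
    list(models = models, genome = genome,
         gtf = do.call(rbind, gtfRows), truth = truth, config = config,
         seed = seed)
}

#' Write a simulation to FASTA + GTF + truth TSV
#'
#' Files are byte-identical across runs with the same seed.
#'
#' @param sim output of [simulateTranscriptome()].
#' @param dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "genome.fa")
    gtf <- file.path(dir, "annotation.gtf")
    tsv <- file.path(dir, "truth.tsv")
    Biostrings::writeXStringSet(sim$genome, fa)
    g <- sim$gtf
    writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                       g$seqname, g$source, g$feature, g$start, g$end,
                       g$score, g$strand, g$frame, g$attributes), gtf)
    write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(fasta = fa, gtf = gtf, truth = tsv))
}

# transcript-coordinate positions of synonymously mutable bases in planted
# regions whose native codon follows the class-consistent bias
.supportingPositions <- function(sim) {
    models <- sim$models
    out <- setNames(vector("list", length(models)), txId(models))
    tab <- .mutableTable()
    for (r in which(!is.na(sim$truth$class))) {
        tx <- sim$truth$txId[r]
        def <- .CLASS_DEFS[[sim$truth$class[r]]]
        cds <- as.character(cdsSeqs(models[tx]))[[1]]
        cs <- sim$truth$cdsStart[r]
        cod0 <- (sim$truth$regionStart[r] - cs) %/% 3L
        cod1 <- (sim$truth$regionEnd[r] - cs) %/% 3L
        codons <- .codonsOf(cds)
        pos <- integer(0)
        for (ci in cod0:(cod1 - 1L)) {
            cod <- codons[ci + 1L]
            aa <- .GC[[cod]]
            pref <- def$pref[[aa]]
            if (is.null(pref) || !cod %in% pref) next
            for (off in names(tab[[cod]]))
                pos <- c(pos, cs + 3L * ci + as.integer(off))
        }
        out[[tx]] <- pos
    }
    out
}

#' Simulate k-mer contribution profiles from planted regimes
#'
#' Draws per-region k-mer fraction vectors directly: each class's regime
#' centre is the k-mer contribution profile of a long fully biased planted
#' stretch of that class, and regions are Dirichlet draws around it
#' (concentration controls within-regime spread). Noise regions are sparse
#' Dirichlet draws over random k-mers, so they scatter rather than cluster.
#' Used to exercise the clustering stage at scale without simulating
#' thousands of transcripts.
#'
#' @param nPerClass regions per class (default 300).
#' @param classes planted classes (default GA, CAG, C).
#' @param noiseFraction extra noise regions as a fraction of the regime
#'   total (default 0.1).
#' @param concentration Dirichlet concentration around the regime centre
#'   (default 50; higher = tighter regimes).
#' @param seed integer seed.
#' @return list with `fractions` (regions x k-mers matrix, rows sum to 1),
#'   `totalRaw` (region score masses, arbitrary units) and `truth` (class
#'   label per region; `"noise"` for noise regions).
#' @export
simulateRegionProfiles <- function(nPerClass = 300L,
                                   classes = c("GA", "CAG", "C"),
                                   noiseFraction = 0.1,
                                   concentration = 50, seed) {
    set.seed(seed)
    centres <- lapply(classes, function(cls) {
        cds <- paste(.plantedCodons(cls, 400L, bias = 1), collapse = "")
        kmerContributionFractions(cds, germScore(cds), 0L, nchar(cds))
    })
    names(centres) <- classes
    nNoise <- round(nPerClass * length(classes) * noiseFraction)
    allK <- sort(unique(unlist(lapply(centres, names))))
    rdirichlet1 <- function(alpha) {
        g <- rgamma(length(alpha), shape = alpha)
        g / sum(g)
    }
    rows <- list(); truth <- character(0)
    for (cls in classes) {
        p0 <- centres[[cls]]
        for (i in seq_len(nPerClass)) {
            v <- rdirichlet1(p0 * concentration + 1e-3)
            rows[[length(rows) + 1L]] <- setNames(v, names(p0))
            truth <- c(truth, cls)
        }
    }
    kmerUniverse <- apply(expand.grid(rep(list(.BASES), 5L))[, 5:1], 1L,
                          paste, collapse = "")
    for (i in seq_len(nNoise)) {
        sup <- sample(kmerUniverse, 20L)
        v <- rdirichlet1(rep(1, 20L))
        rows[[length(rows) + 1L]] <- setNames(v, sup)
        truth <- c(truth, "noise")
    }
    allK <- sort(unique(unlist(lapply(rows, names))))
    m <- matrix(0, length(rows), length(allK),
                dimnames = list(NULL, allK))
    for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
    list(fractions = m,
         totalRaw = rlnorm(length(rows), log(100), 0.5),
         truth = truth)
}

#' Simulate a conservation track with a planted codon-support effect
#'
#' Per-base Gaussian noise around a baseline, with `delta` added at
#' synonymously mutable positions (inside planted regions) whose native
#' codon follows the class-consistent bias — emulating elevated
#' evolutionary constraint on multivalency-supporting codon choices.
#'
#' @param sim output of [simulateTranscriptome()].
#' @param delta planted effect size.
#' @param noiseSd Gaussian noise sd (default 0.1).
#' @param baseline baseline conservation (default 0.5).
#' @param seed integer seed.
#' @return named list of per-transcript numeric tracks.
#' @export
simulateConservation <- function(sim, delta, noiseSd = 0.1, baseline = 0.5,
                                 seed) {
    set.seed(seed)
    supp <- .supportingPositions(sim)
    L <- Biostrings::width(splicedSeqs(sim$models))
    out <- lapply(seq_along(L), function(i) {
        v <- baseline + rnorm(L[i], 0, noiseSd)
        p <- supp[[txId(sim$models)[i]]]
        if (length(p)) v[p + 1L] <- v[p + 1L] + delta
        v
    })
    setNames(out, txId(sim$models))
}

#' Simulate crosslink tracks
#'
#' Multinomial placement of `totalCounts` crosslinks over the CDS (or whole
#' transcript) positions of the simulated set, either uniformly or enriched
#' by `factor` inside planted regions (optionally of selected classes) —
#' emulating a multivalency-preferring versus indifferent RBP.
#'
#' @param sim output of [simulateTranscriptome()].
#' @param sampleId sample label for the output rows.
#' @param model `"uniform"` or `"region"`.
#' @param factor enrichment factor inside planted regions (model
#'   `"region"`).
#' @param totalCounts total crosslinks to place.
#' @param classes planted classes to enrich (default: all).
#' @param scope place crosslinks over `"cds"` (default) or the whole
#'   `"transcript"`.
#' @param seed integer seed.
#' @return long data frame (`txId`, `pos`, `count`, `sampleId`).
#' @export
simulateCrosslinks <- function(sim, sampleId, model = c("uniform", "region"),
                               factor = 5, totalCounts = 1e4, classes = NULL,
                               scope = c("cds", "transcript"), seed) {
    model <- match.arg(model); scope <- match.arg(scope)
    set.seed(seed)
    models <- sim$models
    ids <- txId(models)
    L <- Biostrings::width(splicedSeqs(models))
    cs <- cdsStart(models); ce <- cdsEnd(models)
    posTx <- list(); w <- list()
    for (i in seq_along(ids)) {
        p <- if (scope == "cds") cs[i]:(ce[i] - 1L) else 0:(L[i] - 1L)
        wi <- rep(1, length(p))
        if (model == "region") {
            tr <- sim$truth[sim$truth$txId == ids[i], ]
            if (!is.na(tr$class) &&
                (is.null(classes) || tr$class %in% classes)) {
                hit <- p >= tr$regionStart & p < tr$regionEnd
                wi[hit] <- factor
            }
        }
        posTx[[i]] <- p; w[[i]] <- wi
    }
    wAll <- unlist(w)
    counts <- as.integer(rmultinom(1L, size = totalCounts,
                                   prob = wAll / sum(wAll)))
    df <- data.frame(txId = rep(ids, lengths(posTx)),
                     pos = unlist(posTx), count = counts,
                     sampleId = sampleId)
    df[df$count > 0L, , drop = FALSE]
}
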