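#' @include AllClasses.R
NULL

# Sniff GTF vs GFF3 from attribute-column syntax (key "value"; vs key=value).
.annotationDialect <- function(path) {
    lines <- readLines(path, n = 200L)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (!length(lines)) stop("annotation file has no feature lines: ", path)
    attr9 <- vapply(strsplit(lines, "\t", fixed = TRUE),
                    function(f) if (length(f) >= 9L) f[9L] else "", "")
    if (any(grepl('\\w+ +"', attr9))) "gtf"
    else if (any(grepl("\\w+=", attr9))) "gff3"
    else stop("cannot detect GTF/GFF3 dialect of ", path)
}

# Normalize the imported annotation into exon/CDS tables carrying
# transcript_id and gene_id whichever dialect was used.
.annotationTable <- function(gr, dialect) {
    mc <- S4Vectors::mcols(gr)
    if (dialect == "gtf") {
        txid <- mc$transcript_id
        gid <- mc$gene_id
    } else {
        strip <- function(x) sub("^(transcript|gene):", "", x)
        parent <- sapply(as.list(mc$Parent),
                         function(p) if (length(p)) strip(p[[1L]]) else NA_character_)
        txid <- if (!is.null(mc$transcript_id)) mc$transcript_id else parent
        txid[is.na(txid)] <- parent[is.na(txid)]
        # gene id of a transcript feature is its Parent; exons/CDS inherit it
        isTx <- mc$type %in% c("mRNA", "transcript")
        txGene <- setNames(parent[isTx],
                           strip(as.character(mc$ID[isTx])))
        gid <- if (!is.null(mc$gene_id)) mc$gene_id else txGene[txid]
        gid[is.na(gid)] <- txGene[txid[is.na(gid)]]
    }
    data.frame(seqnames = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               type = as.character(mc$type), txId = txid, geneId = gid,
               stringsAsFactors = FALSE)
}

#' Load spliced transcript models from FASTA + GTF/GFF3
#'
#' Resolves each annotated transcript into its spliced sequence (transcript
#' orientation; minus-strand transcripts are reverse-complemented) and
#' projects the CDS into 0-based half-open spliced-transcript coordinates.
#' The annotation dialect (GTF or GFF3) is auto-detected from the attribute
#' column. U is canonicalized to T.
#'
#' @param fastaPath FASTA of the sequences the annotation refers to
#'   (chromosomes or loci).
#' @param annotationPath GTF or GFF3 with `exon` and `CDS` features.
#' @return a [TranscriptModels]. Transcripts whose CDS length is not
#'   divisible by 3 are skipped with a warning; an annotated transcript
#'   whose sequence is missing from the FASTA is a hard error.
#' @export
readTranscriptModels <- function(fastaPath, annotationPath) {
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))
    dialect <- .annotationDialect(annotationPath)
    gr <- rtracklayer::import(annotationPath, format = dialect)
    tab <- .annotationTable(gr, dialect)
    exons <- tab[tab$type == "exon", ]
    cds <- tab[tab$type == "CDS", ]
    if (!nrow(exons)) stop("annotation contains no exon features")

    txIds <- unique(exons$txId)
    out <- list()
    for (tx in txIds) {
        ex <- exons[exons$txId == tx, ]
        cd <- cds[cds$txId == tx, ]
        if (!nrow(cd)) next
        chr <- unique(ex$seqnames)
        strand <- unique(ex$strand)
        if (length(chr) != 1L || length(strand) != 1L) {
            warning("transcript ", tx, " spans multiple sequences/strands; skipped")
            next
        }
        if (!chr %in% names(genome))
            stop("sequence '", chr, "' for transcript '", tx,
                 "' is missing from the FASTA")
        minus <- strand == "-"
        ex <- ex[order(ex$start, decreasing = minus), ]
        chunks <- Biostrings::DNAStringSet(vapply(seq_len(nrow(ex)), function(i)
            as.character(Biostrings::subseq(genome[[chr]], ex$start[i], ex$end[i])),
            ""))
        splicedPlus <- Biostrings::DNAString(
            paste(as.character(if (minus) rev(chunks) else chunks), collapse = ""))
        spliced <- if (minus) Biostrings::reverseComplement(splicedPlus)
                   else splicedPlus

        # transcript-space offsets of exons in 5'->3' order
        widths <- ex$end - ex$start + 1L
        offsets <- cumsum(c(0L, widths))[seq_along(widths)]
        # first CDS base in genomic coordinates (strand-aware)
        g1 <- if (minus) max(cd$end) else min(cd$start)
        hit <- which(ex$start <= g1 & g1 <= ex$end)
        if (length(hit) != 1L) {
            warning("CDS start of ", tx, " falls outside its exons; skipped")
            next
        }
        cdsStartTx <- offsets[hit] +
            if (minus) ex$end[hit] - g1 else g1 - ex$start[hit]
        cdsLen <- sum(cd$end - cd$start + 1L)
        if (cdsLen %% 3L != 0L) {
            warning("CDS length of ", tx, " is not divisible by 3; skipped")
            next
        }
        seqChar <- chartr("Uu", "Tt", toupper(as.character(spliced)))
        out[[tx]] <- list(seq = seqChar, gene = unique(cd$geneId)[1L],
                          exonLengths = as.integer(widths),
                          cdsStart = as.integer(cdsStartTx),
                          cdsEnd = as.integer(cdsStartTx + cdsLen),
                          spliced = nrow(ex) >= 2L)
    }
    if (!length(out)) stop("no usable transcripts in ", annotationPath)
    seqs <- Biostrings::DNAStringSet(vapply(out, `[[`, "", "seq"))
    names(seqs) <- names(out)
    new("TranscriptModels", seqs = seqs,
        geneId = vapply(out, `[[`, "", "gene"),
        exonLengths = lapply(out, `[[`, "exonLengths"),
        cdsStart = vapply(out, `[[`, 0L, "cdsStart"),
        cdsEnd = vapply(out, `[[`, 0L, "cdsEnd"),
        spliced = vapply(out, `[[`, FALSE, "spliced"))
}

#' Select one representative transcript per gene
#'
#' Keeps, per gene, the transcript with the longest CDS, breaking ties by
#' the longest total transcript length (and then transcript id, for
#' determinism). Unspliced (single-exon) transcripts are excluded before
#' selection; a gene left with no spliced coding transcript is omitted with
#' a message. The operation is idempotent and order-independent.
#'
#' @param models a [TranscriptModels].
#' @return a [TranscriptModels] with exactly one transcript per gene.
#' @export
selectPrimaryTranscripts <- function(models) {
    stopifnot(is(models, "TranscriptModels"))
    keep <- isSpliced(models)
    dropped <- unique(geneId(models)[!keep])
    models <- models[which(keep)]
    lost <- setdiff(dropped, geneId(models))
    if (length(lost))
        message(length(lost), " gene(s) without a spliced coding transcript omitted")
    if (!length(models)) return(models)
    cdsLen <- cdsEnd(models) - cdsStart(models)
    totLen <- Biostrings::width(splicedSeqs(models))
    ord <- order(geneId(models), -cdsLen, -totLen, txId(models))
    first <- ord[!duplicated(geneId(models)[ord])]
    models[sort(first)]
}

#' Write / read called regions as BED-like TSV
#'
#' Six tab-separated columns: transcript id, start, end (0-based half-open
#' transcript coordinates), region id, score (mean smoothed GeRM) and
#' cluster label. The pair round-trips losslessly (k-mer fraction matrices
#' are not serialized).
#'
#' @param regions a [GermRegions].
#' @param path output file.
#' @export
writeRegions <- function(regions, path) {
    stopifnot(is(regions, "GermRegions"))
    gr <- regionRanges(regions)
    mc <- S4Vectors::mcols(gr)
    if (anyDuplicated(mc$regionId))
        stop("duplicate region ids: ",
             paste(unique(mc$regionId[duplicated(mc$regionId)]), collapse = ", "))
    df <- data.frame(txId = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     regionId = mc$regionId,
                     score = mc$meanSmoothed,
                     cluster = as.character(mc$cluster))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRegions
#' @return `readRegions` returns a [GermRegions] (without k-mer fractions).
#' @export
readRegions <- function(path) {
    df <- read.delim(path, colClasses = c("character", "integer", "integer",
                                          "character", "numeric", "character"))
    gr <- GenomicRanges::GRanges(df$txId,
                                 IRanges::IRanges(df$start + 1L, df$end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        regionId = df$regionId, meanSmoothed = df$score,
        totalRaw = rep(NA_real_, nrow(df)), cluster = df$cluster)
    new("GermRegions", ranges = gr,
        kmerFractions = matrix(numeric(0), nrow = 0, ncol = 0))
}

#' Conservation track I/O
#'
#' bedGraph-like per-base TSV (transcript id, 0-based position, value).
#' Positions absent from the file are missing (NA), never zero.
#'
#' @param cons named list of per-transcript numeric vectors (NA = missing).
#' @param path file path.
#' @export
writeConservation <- function(cons, path) {
    rows <- lapply(names(cons), function(tx) {
        v <- cons[[tx]]
        ok <- !is.na(v)
        data.frame(txId = tx, pos = which(ok) - 1L, value = v[ok])
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' @rdname writeConservation
#' @param models a [TranscriptModels] giving the transcript lengths used to
#'   densify the sparse rows.
#' @export
readConservation <- function(path, models) {
    df <- read.delim(path, colClasses = c("character", "integer", "numeric"))
    L <- setNames(Biostrings::width(splicedSeqs(models)), txId(models))
    out <- lapply(txId(models), function(tx) {
        v <- rep(NA_real_, L[[tx]])
        sub <- df[df$txId == tx, ]
        v[sub$pos + 1L] <- sub$value
        v
    })
    setNames(out, txId(models))
}

#' Crosslink track I/O
#'
#' BED-like long TSV with columns `txId`, `pos` (0-based transcript
#' coordinate), `count` (non-negative integer) and `sampleId`. This long
#' data frame is the in-memory exchange format of all CLIP statistics.
#'
#' @param crosslinks data frame with the four columns above.
#' @param path file path.
#' @export
writeCrosslinks <- function(crosslinks, path) {
    stopifnot(all(c("txId", "pos", "count", "sampleId") %in% names(crosslinks)))
    if (any(crosslinks$count < 0)) stop("crosslink counts must be >= 0")
    write.table(crosslinks, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeCrosslinks
#' @export
readCrosslinks <- function(path) {
    read.delim(path, colClasses = c("character", "integer", "integer",
                                    "character"))
}

#' Read an RBP motif enrichment table
#'
#' TSV with columns `rbp`, `kmer` and `rScore` (RBNS-style per-k-mer
#' enrichment).
#'
#' @param path file path.
#' @return data frame with those columns.
#' @export
readMotifTable <- function(path) {
    df <- read.delim(path)
    stopifnot(all(c("rbp", "kmer", "rScore") %in% names(df)))
    df
}

#' Write score tracks as per-position TSV
#'
#' Long format: transcript id, 0-based k-mer start position, raw,
#' normalized and smoothed score (NA where a layer has not been computed).
#'
#' @param tracks a [GermTracks].
#' @param path file path.
#' @export
writeTracks <- function(tracks, path) {
    stopifnot(is(tracks, "GermTracks"))
    rows <- lapply(seq_along(tracks@txId), function(i) {
        r <- tracks@raw[[i]]
        n <- length(r)
        data.frame(txId = tracks@txId[i], pos = seq_len(n) - 1L, raw = r,
                   normalized = if (length(tracks@normalized))
                       tracks@normalized[[i]] else rep(NA_real_, n),
                   smoothed = if (length(tracks@smoothed))
                       tracks@smoothed[[i]] else rep(NA_real_, n))
    })
    write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}
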