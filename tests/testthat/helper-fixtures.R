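# Shared fixture builders (everything is generated in code at test time).

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# a CDS with a planted class-specific multivalent stretch; returns the CDS
# and the planted interval in CDS coordinates (0-based half-open)
plantedCds <- function(class = "GA", bgCodons = 300L, plantCodons = NULL,
                       bias = 0.9) {
    if (is.null(plantCodons)) plantCodons <- sample(84:133, 1L)
    at <- sample(10:(bgCodons - 10L), 1L)
    bg <- germkit:::.backgroundCodons(bgCodons)
    pl <- germkit:::.plantedCodons(class, plantCodons, bias)
    cds <- paste(c("ATG", bg[seq_len(at)], pl, bg[(at + 1L):bgCodons], "TAA"),
                 collapse = "")
    list(cds = cds, start = 3L * (at + 1L),
         end = 3L * (at + 1L) + 3L * plantCodons)
}

# write a minimal FASTA + GTF pair for hand-constructed loci
writeToyAnnotation <- function(dir, chrs, rows) {
    fa <- file.path(dir, "toy.fa")
    gtf <- file.path(dir, "toy.gtf")
    writeLines(unlist(lapply(names(chrs), function(ch)
        c(paste0(">", ch), chrs[[ch]]))), fa)
    writeLines(sprintf("%s\ttoy\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       rows$seqname, rows$feature, rows$start, rows$end,
                       rows$strand, rows$attributes), gtf)
    list(fasta = fa, gtf = gtf)
}

gtfAttr <- function(gene, tx) sprintf('gene_id "%s"; transcript_id "%s";',
                                      gene, tx)

revcomp <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))

# truth regions of a simulation as a GermRegions object
truthRegions <- function(sim) {
    truth <- sim$truth[!is.na(sim$truth$class), ]
    gr <- GenomicRanges::GRanges(
        truth$txId,
        IRanges::IRanges(truth$regionStart + 1L, truth$regionEnd))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        regionId = paste0("truth", seq_len(nrow(truth))),
        meanSmoothed = NA_real_, totalRaw = NA_real_,
        cluster = truth$class)
    new("GermRegions", ranges = gr,
        kmerFractions = matrix(numeric(0), 0, 0))
}

# fraction of planted truth regions overlapped by at least one called region
plantedRecall <- function(regions, truth) {
    truth <- truth[!is.na(truth$class), ]
    gr <- regionRanges(regions)
    hits <- vapply(seq_len(nrow(truth)), function(r) {
        g <- gr[as.character(GenomicRanges::seqnames(gr)) == truth$txId[r]]
        length(g) > 0 &&
            any(GenomicRanges::start(g) - 1L < truth$regionEnd[r] &
                GenomicRanges::end(g) > truth$regionStart[r])
    }, FALSE)
    mean(hits)
}
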