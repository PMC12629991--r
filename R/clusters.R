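#' @include AllClasses.R core.R
NULL

# a, b parameters of the low-dimensional similarity curve 1/(1 + a x^(2b)),
# fitted so the curve tracks exp(-(x - minDist)) beyond minDist
.abFromMinDist <- function(minDist, spread = 1) {
    xs <- seq(0, spread * 3, length.out = 300L)
    ys <- ifelse(xs < minDist, 1, exp(-(xs - minDist) / spread))
    fit <- tryCatch(
        nls(ys ~ 1 / (1 + a * xs^(2 * b)), start = list(a = 1.9, b = 0.8)),
        error = function(e) NULL)
    if (is.null(fit)) c(a = 1.93, b = 0.79) else coef(fit)
}

# smooth-kNN calibration: per point, rho = nearest-neighbour distance and
# sigma solving sum_j exp(-(d_ij - rho)/sigma) = log2(k)
.fuzzyGraph <- function(d, nNeighbors) {
    n <- nrow(d)
    target <- log2(nNeighbors)
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    for (i in seq_len(n)) {
        di <- d[i, -i]
        ord <- order(di)[seq_len(nNeighbors)]
        dk <- di[ord]
        nbr <- which(seq_len(n) != i)[ord]
        rho <- dk[1L]
        lo <- 0; hi <- Inf; sigma <- 1
        for (it in 1:64) {
            val <- sum(exp(-pmax(0, dk - rho) / sigma))
            if (abs(val - target) < 1e-5) break
            if (val > target) { hi <- sigma; sigma <- (lo + hi) / 2 }
            else { lo <- sigma
                   sigma <- if (is.finite(hi)) (lo + hi) / 2 else sigma * 2 }
        }
        ii <- c(ii, rep(i, nNeighbors)); jj <- c(jj, nbr)
        ww <- c(ww, exp(-pmax(0, dk - rho) / sigma))
    }
    # symmetrize by fuzzy union: w = w1 + w2 - w1 w2
    W <- matrix(0, n, n)
    W[cbind(ii, jj)] <- ww
    Wt <- t(W)
    W <- W + Wt - W * Wt
    W
}

#' Nonlinear embedding of k-mer contribution profiles
#'
#' A compact UMAP implementation: exact k-nearest-neighbour graph with
#' smooth-kNN membership calibration, fuzzy-union symmetrization, spectral
#' initialization from the normalized graph Laplacian, and stochastic
#' gradient optimization of the fuzzy cross-entropy with negative sampling
#' (compiled). Deterministic under `seed`.
#'
#' @param x numeric matrix (observations x features).
#' @param nComponents embedding dimensionality (default 4).
#' @param nNeighbors neighbourhood size (default 50).
#' @param minDist minimum embedding distance parameter (default 0.001).
#' @param nEpochs optimization epochs (default 200).
#' @param attractEpochs optional extra attraction-only annealing epochs
#'   after the main optimization, contracting each cluster (default 0 =
#'   disabled; the standard layout is used as is).
#' @param seed integer seed (required: the layout is stochastic).
#' @return numeric matrix (observations x `nComponents`).
#' @export
umapEmbed <- function(x, nComponents = 4L, nNeighbors = 50L,
                      minDist = 0.001, nEpochs = 200L, attractEpochs = 0L,
                      seed) {
    x <- as.matrix(x)
    n <- nrow(x)
    nNeighbors <- min(nNeighbors, n - 1L)
    if (n < 10L) stop("too few observations to embed")
    set.seed(seed)
    d <- as.matrix(dist(x))
    W <- .fuzzyGraph(d, nNeighbors)

    # spectral init: eigenvectors of the symmetric normalized Laplacian for
    # the smallest non-trivial eigenvalues
    deg <- pmax(rowSums(W), 1e-12)
    Dhalf <- 1 / sqrt(deg)
    Lsym <- diag(n) - (Dhalf * W) %*% diag(Dhalf)
    es <- eigen(Lsym, symmetric = TRUE)
    take <- seq(n - 1L, by = -1L, length.out = nComponents)
    emb <- es$vectors[, take, drop = FALSE]
    emb <- emb / max(abs(emb)) * 10
    emb <- emb + matrix(rnorm(n * nComponents, sd = 1e-4), n)

    keep <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
    head <- c(keep[, 1L], keep[, 2L]) - 1L
    tail <- c(keep[, 2L], keep[, 1L]) - 1L
    wts <- c(W[keep], W[keep])
    ab <- .abFromMinDist(minDist)
    emb <- .umap_layout_cpp(emb, as.integer(head), as.integer(tail), wts,
                            ab[[1L]], ab[[2L]], as.integer(nEpochs), 1.0,
                            1.0, 5L)
    if (attractEpochs > 0L) {
        # attraction-only annealing: contracts each connected neighbourhood
        # smoothly, removing the micro-clumping the negative-sampling SGD
        # leaves inside clusters (separation is preserved: there are no
        # edges between well-separated groups to attract them)
        emb <- .umap_layout_cpp(emb, as.integer(head), as.integer(tail),
                                wts, ab[[1L]], ab[[2L]],
                                as.integer(attractEpochs), 0.2, 1.0, 0L)
    }
    dimnames(emb) <- list(rownames(x), NULL)
    emb
}

#' OPTICS reachability analysis
#'
#' Standard OPTICS ordering with core distances at `minPts`: returns the
#' visit order and reachability distance of each point, from which flat
#' density clusterings at any threshold can be extracted.
#'
#' @param x numeric matrix (observations x dims) or a `dist`.
#' @param minPts minimum number of points for a core (including the point
#'   itself).
#' @return list with `order` (visit order), `reachability` (in visit
#'   order; first point of each component is `Inf`) and `coreDist`.
#' @export
opticsReachability <- function(x, minPts) {
    d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(dist(x))
    n <- nrow(d)
    stopifnot(minPts >= 2L, n >= minPts)
    core <- apply(d, 1L, function(r) sort(r)[minPts])  # includes self (0)
    reach <- rep(Inf, n)
    processed <- rep(FALSE, n)
    ord <- integer(n)
    for (step in seq_len(n)) {
        cand <- which(!processed)
        p <- cand[which.min(reach[cand])]
        if (!is.finite(reach[p])) p <- cand[which.min(core[cand])]
        ord[step] <- p
        processed[p] <- TRUE
        newReach <- pmax(core[p], d[p, ])
        upd <- !processed & newReach < reach
        reach[upd] <- newReach[upd]
    }
    list(order = ord, reachability = reach[ord], coreDist = core)
}

#' Knee of the reachability profile
#'
#' Scans candidate thresholds from the 99th percentile of the reachability
#' distances down to 0 and tracks the proportion of points below each
#' threshold; the knee is the first threshold (scanning downward) at which
#' the first derivative of that curve reaches 40% of its maximum.
#'
#' @param reachability finite reachability values (Inf entries ignored).
#' @param fromQuantile upper end of the scan (default 0.99).
#' @param fraction derivative fraction defining the knee (default 0.4).
#' @param steps grid resolution (default 512).
#' @return the threshold.
#' @export
kneeThreshold <- function(reachability, fromQuantile = 0.99,
                          fraction = 0.4, steps = 512L) {
    r <- reachability[is.finite(reachability)]
    ts <- seq(quantile(r, fromQuantile, names = FALSE), 0,
              length.out = steps)
    prop <- vapply(ts, function(t) mean(r < t), 0)
    deriv <- abs(diff(prop) / diff(ts))
    # the empirical derivative is a histogram estimate; smooth it so the
    # 40% rule responds to the bulk density profile, not to single-bin
    # spikes from coincident points
    deriv <- smoothTrack(deriv, 31L)
    dmax <- max(deriv)
    hit <- which(deriv >= fraction * dmax)[1L]
    ts[hit]   # upper endpoint of the first qualifying interval
}

# Flat cut of the reachability plot (the OPTICS -> DBSCAN handoff).
# Membership is cut at the knee threshold; a *boundary* between clusters
# additionally requires the reachability spike to exceed `sepThreshold`.
# At modest region counts the within-cluster reachability tail overlaps
# any bulk-derived threshold and a strict DBSCAN extraction shatters
# clusters; spikes between the two thresholds are therefore treated as
# intra-cluster density fluctuations: the spiking point becomes noise but
# the band continues. Between well-separated k-mer classes the reachability
# jumps by an order of magnitude, so the boundary rule is insensitive to
# the exact multiple used.
.extractClusters <- function(ord, reach, core, threshold, minPts,
                             sepThreshold = Inf, d = NULL) {
    n <- length(ord)
    labels <- rep(-1L, n)
    cur <- 0L
    sepT <- max(threshold, sepThreshold)
    pending <- TRUE   # a boundary has been seen; next dense point opens a cluster
    for (i in seq_len(n)) {
        p <- ord[i]
        if (reach[i] > sepT) pending <- TRUE
        if (pending) {
            if (core[p] <= threshold) {
                cur <- cur + 1L
                labels[p] <- cur
                pending <- FALSE
            }                      # else stays noise until a dense point
        } else if (reach[i] <= threshold) {
            labels[p] <- cur
        }                          # sub-ceiling spikes: noise, band continues
    }
    # DBSCAN border rule, widened to the separation scale: a noise point
    # within `sepThreshold` of a clustered core point joins that cluster
    # (distances below the separation threshold are intra-cluster by the
    # boundary rule above)
    if (!is.null(d)) {
        coreIdx <- which(labels > 0L & core <= threshold)
        radius <- if (is.finite(sepThreshold)) sepThreshold else threshold
        for (p in which(labels == -1L)) {
            dp <- d[p, coreIdx]
            j <- which.min(dp)
            if (length(j) && dp[j] <= radius) labels[p] <- labels[coreIdx[j]]
        }
    }
    # clusters smaller than minPts are noise
    for (cl in unique(labels[labels > 0L]))
        if (sum(labels == cl) < minPts) labels[labels == cl] <- -1L
    # renumber by decreasing size
    sizes <- sort(table(labels[labels > 0L]), decreasing = TRUE)
    map <- setNames(seq_along(sizes), names(sizes))
    ifelse(labels > 0L, map[as.character(labels)], -1L)
}

#' Cluster GeRM regions into multivalency classes
#'
#' Embeds the per-region k-mer contribution profiles into 4 dimensions
#' ([umapEmbed()]), orders them by density ([opticsReachability()] with
#' `minPts` equal to 1% of the region count), and cuts the reachability
#' plot at the knee-derived threshold ([kneeThreshold()]). Points outside
#' any cluster are labelled -1 and excluded from downstream summaries. The
#' number of clusters is an outcome, never a parameter.
#'
#' @param x a [GermRegions] or a numeric matrix of k-mer fractions.
#' @param nComponents,nNeighbors,minDist,nEpochs see [umapEmbed()].
#' @param minPointsFrac fraction of regions defining the OPTICS core size
#'   (default 0.01).
#' @param sepFactor a cluster boundary requires a reachability spike above
#'   `sepFactor` times the knee threshold (default 3); smaller spikes are
#'   within-cluster density fluctuations (the point becomes noise).
#' @param seed integer seed (mandatory; the embedding is stochastic).
#' @return a [MultivalencyClasses]. When `x` is a [GermRegions] the labels
#'   are also written into its `cluster` metadata column of the returned
#'   object's `regions` attribute.
#' @export
clusterRegions <- function(x, nComponents = 4L, nNeighbors = 50L,
                           minDist = 0.001, nEpochs = 200L,
                           minPointsFrac = 0.01, sepFactor = 3, seed) {
    kf <- if (is(x, "GermRegions")) kmerFractions(x) else as.matrix(x)
    n <- nrow(kf)
    minPts <- max(2L, round(minPointsFrac * n))
    if (n < max(200L, minPts * 10L))
        stop("too few regions (", n, ") for a meaningful ", minPointsFrac * 100,
             "% density rule; supply at least ", max(200L, minPts * 10L),
             " regions")
    emb <- umapEmbed(kf, nComponents, nNeighbors, minDist, nEpochs,
                     seed = seed)
    opt <- opticsReachability(emb, minPts)
    thr <- kneeThreshold(opt$reachability)
    labels <- .extractClusters(opt$order, opt$reachability, opt$coreDist,
                               thr, minPts, sepThreshold = sepFactor * thr,
                               d = as.matrix(dist(emb)))
    new("MultivalencyClasses", labels = as.integer(labels), embedding = emb,
        reachability = opt$reachability, order = opt$order, threshold = thr,
        representativeKmers = list(),
        params = list(nComponents = nComponents, nNeighbors = nNeighbors,
                      minDist = minDist, nEpochs = nEpochs,
                      minPointsFrac = minPointsFrac, sepFactor = sepFactor,
                      seed = seed))
}

#' Representative k-mers per multivalency class
#'
#' Pools each cluster's k-mer multivalency mass (region fractions weighted
#' by region total raw score), sorts k-mers by decreasing proportion (ties
#' broken lexicographically) and keeps the minimal prefix whose cumulative
#' proportion reaches `coverage` (default 50%). With `dedupe = TRUE` a
#' k-mer appearing in several clusters' lists is retained only in the
#' cluster where its contribution proportion is highest (the feature-table
#' convention, ensuring no k-mer overlaps between clusters).
#'
#' @param regions a [GermRegions] with k-mer fractions.
#' @param classes a [MultivalencyClasses] (or an integer label vector).
#' @param coverage cumulative proportion to cover (default 0.5).
#' @param dedupe drop cross-cluster duplicates (default FALSE).
#' @return named list: cluster label -> ordered character vector of k-mers.
#' @export
representativeKmers <- function(regions, classes, coverage = 0.5,
                                dedupe = FALSE) {
    labels <- if (is(classes, "MultivalencyClasses")) clusterLabels(classes)
              else as.integer(classes)
    kf <- kmerFractions(regions)
    stopifnot(length(labels) == nrow(kf))
    tot <- S4Vectors::mcols(regionRanges(regions))$totalRaw
    mass <- kf * tot
    clusters <- sort(unique(labels[labels > 0L]))
    props <- list(); sets <- list()
    for (cl in clusters) {
        m <- colSums(mass[labels == cl, , drop = FALSE])
        p <- m / sum(m)
        ordp <- order(-p, colnames(kf))
        p <- p[ordp]
        cum <- cumsum(p)
        takeN <- which(cum >= coverage)[1L]
        sets[[as.character(cl)]] <- names(p)[seq_len(takeN)]
        props[[as.character(cl)]] <- p
    }
    if (dedupe && length(sets) > 1L) {
        all <- unlist(sets, use.names = FALSE)
        dup <- unique(all[duplicated(all)])
        for (km in dup) {
            inCl <- names(sets)[vapply(sets, function(s) km %in% s, FALSE)]
            best <- inCl[which.max(vapply(inCl, function(cl)
                props[[cl]][[km]], 0))]
            for (cl in setdiff(inCl, best))
                sets[[cl]] <- setdiff(sets[[cl]], km)
        }
    }
    sets
}

# per-instance table of CDS k-mers with their raw scores
.cdsKmerInstances <- function(models, tracks) {
    k <- tracks@params@k
    ids <- tracks@txId
    models <- models[ids]
    seqs <- as.character(splicedSeqs(models))
    L <- Biostrings::width(splicedSeqs(models))
    cs <- cdsStart(models); ce <- cdsEnd(models)
    parts <- lapply(seq_along(ids), function(i) {
        ks <- .cdsKmerStarts(cs[i], ce[i], k, L[i])
        if (!length(ks)) return(NULL)
        kmers <- substring(seqs[i], ks + 1L, ks + k)
        ok <- !grepl("N", kmers, fixed = TRUE)
        data.frame(txId = ids[i], pos = ks[ok], kmer = kmers[ok],
                   raw = tracks@raw[[i]][ks[ok] + 1L])
    })
    do.call(rbind, parts)
}

#' Per-transcript multivalency class scores
#'
#' Raw GeRM scores of every CDS k-mer instance are z-scaled against all
#' other instances of the same k-mer across the supplied set (mean 0, sd
#' 1); a transcript's score for a class is the sum of these scaled scores
#' over the class's representative k-mers within its CDS. Transcripts rich
#' in a class's k-mers *in multivalent contexts* are rewarded; k-mers with
#' zero score variance contribute 0 (logged).
#'
#' @param models a [TranscriptModels].
#' @param tracks the matching raw [GermTracks] (the z-scaling is fitted on
#'   this set).
#' @param repKmers named list of representative k-mers per class (see
#'   [representativeKmers()]).
#' @return data frame: `txId` plus one numeric column per class.
#' @export
transcriptClassScores <- function(models, tracks, repKmers) {
    inst <- .cdsKmerInstances(models, tracks)
    mu <- tapply(inst$raw, inst$kmer, mean)
    sg <- tapply(inst$raw, inst$kmer, sd)
    zeroVar <- is.na(sg) | sg == 0
    if (any(zeroVar))
        message(sum(zeroVar), " k-mer(s) with zero score variance scored as 0")
    inst$z <- ifelse(zeroVar[inst$kmer], 0,
                     (inst$raw - mu[inst$kmer]) / sg[inst$kmer])
    out <- data.frame(txId = tracks@txId)
    for (cl in names(repKmers)) {
        sel <- inst$kmer %in% repKmers[[cl]]
        sums <- tapply(inst$z[sel], factor(inst$txId[sel], levels = out$txId),
                       sum)
        out[[cl]] <- as.numeric(ifelse(is.na(sums), 0, sums))
    }
    out
}

#' Per-transcript feature table for retention modelling
#'
#' CDS length, mean exon length, and per-class CDS multivalency: the summed
#' raw GeRM scores of each class's representative k-mers within the CDS,
#' divided by CDS length and then standard-scaled column-wise over the
#' supplied set (mean 0, sd 1). Highly correlated classes can be merged
#' into a single feature (e.g. a combined GC-rich cluster) via
#' `mergeClusters`; use deduplicated representative sets so no k-mer is
#' counted for two classes.
#'
#' @inheritParams transcriptClassScores
#' @param mergeClusters optional named list, new feature name -> character
#'   vector of class labels to combine (their k-mer sets are unioned).
#' @return data frame: `txId`, `cdsLength`, `meanExonLength`, one scaled
#'   multivalency column per (merged) class.
#' @export
retentionFeatures <- function(models, tracks, repKmers,
                              mergeClusters = NULL) {
    if (!is.null(mergeClusters)) {
        for (nm in names(mergeClusters)) {
            members <- as.character(mergeClusters[[nm]])
            repKmers[[nm]] <- sort(unique(unlist(repKmers[members])))
            repKmers[members] <- NULL
        }
    }
    ids <- tracks@txId
    models <- models[ids]
    inst <- .cdsKmerInstances(models, tracks)
    cdsLen <- cdsEnd(models) - cdsStart(models)
    out <- data.frame(txId = ids, cdsLength = cdsLen,
                      meanExonLength =
                          vapply(exonLengths(models), mean, 0))
    for (cl in names(repKmers)) {
        sel <- inst$kmer %in% repKmers[[cl]]
        sums <- tapply(inst$raw[sel], factor(inst$txId[sel], levels = ids),
                       sum)
        v <- ifelse(is.na(sums), 0, as.numeric(sums)) / cdsLen
        out[[cl]] <- as.numeric(scale(v))
    }
    out
}
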