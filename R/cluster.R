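## Core clustering: seed clusters over identical-barcode read sets, then
## iterative merging of clusters with similar barcodes subject to genotype
## coherence (Jaccard), barcode edit distance and size divergence.

#' Levenshtein edit distance between barcode strings
#'
#' Unit-cost substitution/insertion/deletion distance.
#'
#' @param a,b Character vectors (recycled elementwise).
#' @return Integer vector of distances.
#' @export
barcodeEditDistance <- function(a, b) {
    n <- max(length(a), length(b))
    a <- rep_len(a, n); b <- rep_len(b, n)
    vapply(seq_len(n), function(i)
        as.integer(utils::adist(a[i], b[i])), integer(1))
}

#' Filter putative sequencing errors from pooled candidate variants
#'
#' A candidate variant is dropped only when it is seen in a single read AND
#' its quality is below threshold; support by two or more reads, or adequate
#' quality alone, retains it. The retained variant's quality is the maximum
#' over its supporting reads.
#'
#' @param variants List of per-read candidate-variant data.frames.
#' @param varQualMin Quality threshold (default Q50).
#' @return A candidate-variant data.frame of retained variants.
#' @export
filterVariantErrors <- function(variants, varQualMin = 50L) {
    nz <- variants[vapply(variants, nrow, integer(1)) > 0L]
    if (!length(nz)) return(emptyVariants())
    pool <- do.call(rbind, lapply(seq_along(nz), function(i)
        cbind(nz[[i]], .read = i)))
    key <- paste0(pool$pos, ":", pool$ref, ">", pool$alt)
    support <- vapply(split(pool$.read, key), function(r) length(unique(r)), integer(1))
    maxq <- vapply(split(pool$qual, key), max, integer(1))
    keep <- support >= 2L | maxq >= varQualMin
    if (!any(keep)) return(emptyVariants())
    first <- pool[!duplicated(key), , drop = FALSE]
    fkey <- key[!duplicated(key)]
    sel <- first[fkey %in% names(keep)[keep], , drop = FALSE]
    sel$qual <- unname(maxq[paste0(sel$pos, ":", sel$ref, ">", sel$alt)])
    variantTable(sel$pos, sel$ref, sel$alt, sel$qual, sel$vtype)
}

.jaccardKeys <- function(ka, kb) {
    if (length(ka) == 0L && length(kb) == 0L) return(1)
    length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Seed clusters within an identical-barcode read set
#'
#' Builds a graph over reads sharing one barcode: after pooling the set and
#' filtering sequencing errors, an edge joins two reads if both are WT or if
#' their filtered variant sets have Jaccard index at or above the threshold.
#' Each connected component (including singletons) becomes a seed cluster.
#'
#' @param variants List of per-read candidate-variant data.frames for reads
#'   sharing one identical (virtual) barcode.
#' @param jaccardMin Jaccard threshold (default 0.2).
#' @param varQualMin Quality threshold for the error filter.
#' @return List of integer vectors, the member indices of each seed cluster;
#'   every read appears in exactly one.
#' @export
seedClusters <- function(variants, jaccardMin = 0.2, varQualMin = 50L) {
    n <- length(variants)
    if (n == 1L) return(list(1L))
    retained <- variantKey(filterVariantErrors(variants, varQualMin))
    fsets <- lapply(variants, function(v) intersect(unique(variantKey(v)), retained))
    edges <- NULL
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        ok <- (length(fsets[[i]]) == 0L && length(fsets[[j]]) == 0L) ||
            .jaccardKeys(fsets[[i]], fsets[[j]]) >= jaccardMin
        if (ok) edges <- rbind(edges, c(i, j))
    }
    comp <- unionFindComponents(n, edges)
    unname(split(seq_len(n), comp))
}

#' Size-divergence criterion for a candidate merge
#'
#' Two clusters may merge across barcodes at edit distance `ed` only when
#' their sizes are sufficiently divergent: |log2(size1/size2)| > ed, as
#' expected when the smaller cluster holds reads of the same clone with more
#' barcode basecalling errors.
#'
#' @param size1,size2 Cluster sizes (>= 1).
#' @param ed Edit distance between the clusters' barcodes (>= 1).
#' @return TRUE when the sizes are sufficiently divergent.
#' @export
sizeDivergenceOK <- function(size1, size2, ed) {
    abs(log2(size1 / size2)) > ed
}

## Core merge evaluation; members are indices into the per-read vectors.
.evalMerge <- function(m1, m2, ed, barcodes, variants, maxEd, jaccardMin,
                       varQualMin) {
    u <- c(m1, m2)
    filt <- filterVariantErrors(variants[u], varQualMin)
    retained <- variantKey(filt)
    keysOf <- function(m) intersect(
        unique(unlist(lapply(variants[m], variantKey), use.names = FALSE)),
        retained)
    k1 <- keysOf(m1); k2 <- keysOf(m2)
    aOK <- (length(k1) == 0L && length(k2) == 0L) ||
        .jaccardKeys(k1, k2) >= jaccardMin
    if (!aOK) return(list(accept = FALSE, reason = "a", filt = filt))
    ub <- unique(barcodes[u])
    if (length(ub) > 1L) {
        dm <- utils::adist(ub)
        if (max(dm) > maxEd)
            return(list(accept = FALSE, reason = "b", filt = filt))
    }
    if (!sizeDivergenceOK(length(m1), length(m2), ed))
        return(list(accept = FALSE, reason = "c", filt = filt))
    list(accept = TRUE, reason = "", filt = filt)
}

#' Evaluate a candidate cluster merge
#'
#' Applies the three acceptance criteria to a proposed merge of two clusters
#' whose minimum member-barcode edit distance is `ed`: (a) after re-filtering
#' errors on the pooled candidate cluster, both clusters are WT or their
#' remaining variant sets have Jaccard index >= `jaccardMin`; (b) no pair of
#' member barcodes in the union exceeds `maxEd`; (c) cluster sizes are
#' sufficiently divergent ([sizeDivergenceOK()]).
#'
#' @param members1,members2 Integer indices of the two clusters' reads.
#' @param ed Minimum member-barcode edit distance between the clusters.
#' @param barcodes Character vector of per-read clustering barcodes.
#' @param variants List of per-read candidate-variant data.frames.
#' @param maxEd Maximum allowed barcode edit distance (default 2).
#' @param jaccardMin Jaccard threshold (default 0.2).
#' @param varQualMin Error-filter quality threshold (default Q50).
#' @return List with `accept` (logical), `reason` ("" when accepted,
#'   otherwise the first failed criterion "a"/"b"/"c"), and `filt`, the
#'   error-filtered variant table of the candidate cluster.
#' @export
evaluateMerge <- function(members1, members2, ed, barcodes, variants,
                          maxEd = 2L, jaccardMin = 0.2, varQualMin = 50L) {
    stopifnot(ed >= 1L, ed <= maxEd)
    .evalMerge(members1, members2, ed, barcodes, variants, maxEd,
               jaccardMin, varQualMin)
}

## All strings obtainable from s by deleting up to k characters (unique).
.deletionNeighborhood <- function(s, k) {
    out <- s
    frontier <- s
    for (round in seq_len(k)) {
        nxt <- unique(unlist(lapply(frontier, function(x) {
            n <- nchar(x)
            if (n == 0L) return(character(0))
            vapply(seq_len(n), function(i)
                paste0(substr(x, 1L, i - 1L), substr(x, i + 1L, n)), "")
        }), use.names = FALSE))
        nxt <- setdiff(nxt, out)
        out <- c(out, nxt)
        frontier <- nxt
    }
    out
}

## Candidate barcode pairs at edit distance 1..maxEd among unique barcodes,
## found by symmetric-deletion indexing and verified with exact distances.
## Returns data.frame(i, j, ed) with i < j (indices into ub).
barcodeNeighborPairs <- function(ub, maxEd) {
    if (maxEd < 1L || length(ub) < 2L)
        return(data.frame(i = integer(0), j = integer(0), ed = integer(0)))
    neigh <- lapply(ub, .deletionNeighborhood, k = maxEd)
    owner <- rep(seq_along(ub), lengths(neigh))
    byKey <- split(owner, unlist(neigh, use.names = FALSE))
    byKey <- byKey[lengths(byKey) > 1L]
    if (!length(byKey))
        return(data.frame(i = integer(0), j = integer(0), ed = integer(0)))
    pairs <- unique(do.call(rbind, lapply(byKey, function(o) {
        o <- sort(unique(o))
        if (length(o) < 2L) return(NULL)
        t(utils::combn(o, 2L))
    })))
    ed <- vapply(seq_len(nrow(pairs)), function(r)
        as.integer(utils::adist(ub[pairs[r, 1]], ub[pairs[r, 2]])), integer(1))
    keep <- ed >= 1L & ed <= maxEd
    data.frame(i = pairs[keep, 1], j = pairs[keep, 2], ed = ed[keep])
}

## Plurality consensus over strings with quality/lexicographic tie-breaks.
.plurality <- function(strs, qualTotals) {
    tab <- tapply(rep(1L, length(strs)), strs, sum)
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1L) {
        qt <- tapply(qualTotals, strs, sum)[cand]
        cand <- cand[qt == max(qt)]
    }
    sort(cand, method = "radix")[1]
}

#' Cluster an extracted read library into clones
#'
#' Reads passing upstream filters are grouped by identical (virtual) barcode
#' and seeded into genotype-coherent clusters ([seedClusters()]). Cluster
#' pairs whose members' barcodes lie at minimum edit distance ed are then
#' iteratively considered for merging, for ed = 1 up to `maxEd`; each
#' candidate is accepted or rejected by [evaluateMerge()]. Within an ed
#' level, candidate pairs are processed in deterministic order (descending
#' combined size, then lexicographic consensus-barcode pair, then smallest
#' member read id) and the level is iterated to fixpoint before advancing.
#' Candidate pairs are discovered through a symmetric-deletion barcode index
#' and verified with exact edit distances.
#'
#' @param reads A [ReadExtractions-class].
#' @param maxEd Maximum barcode edit distance for merging (default 2);
#'   `maxEd = 0` returns the seed clustering.
#' @param jaccardMin Jaccard threshold for genotype coherence (default 0.2).
#' @param varQualMin Error-filter quality threshold (default Q50).
#' @param useVirtual Cluster on the virtual (concatenated) barcode (default)
#'   or on the upstream barcode alone.
#' @return A [CloneClusterSet-class]; kept reads form a partition.
#' @export
clusterReads <- function(reads, maxEd = 2L, jaccardMin = 0.2,
                         varQualMin = 50L, useVirtual = TRUE) {
    d <- readData(reads)
    kept <- which(d$keep)
    params <- list(maxEd = maxEd, jaccardMin = jaccardMin,
                   varQualMin = varQualMin, useVirtual = useVirtual)
    bc <- if (useVirtual || is.null(d$barcode2)) d$virtualBarcode else d$barcode1
    bc <- as.character(bc)
    vars <- as.list(d$variants)
    vq <- if (!useVirtual && !is.null(d$barcode2)) d$bcQual1 else {
        if (is.null(d$bcQual2)) d$bcQual1 else paste0(d$bcQual1, d$bcQual2)
    }
    qualTotal <- vapply(vq, function(q)
        if (is.na(q)) 0L else sum(as.integer(charToRaw(q)) - 33L), integer(1))

    newCluster <- function(members) {
        filt <- filterVariantErrors(vars[members], varQualMin)
        list(members = members, size = length(members),
             barcodes = unique(bc[members]), filt = filt,
             isWT = nrow(filt) == 0L,
             cons = .plurality(bc[members], qualTotal[members]),
             minId = min(d$readId[members]))
    }

    ## ---- seed phase
    clusters <- list()
    for (grp in split(kept, bc[kept])) {
        seeds <- seedClusters(vars[grp], jaccardMin, varQualMin)
        clusters <- c(clusters, lapply(seeds, function(s) newCluster(grp[s])))
    }
    auditRows <- list()

    ## ---- merge phase
    if (maxEd >= 1L && length(clusters) > 1L) {
        ub <- sort(unique(bc[kept]), method = "radix")
        bcPairs <- barcodeNeighborPairs(ub, maxEd)

        repeat_level <- function(clusters, ed) {
            repeat {
                nc <- length(clusters)
                if (nc < 2L) return(clusters)
                ## map barcode -> cluster ids
                bcOf <- lapply(clusters, function(cl) match(cl$barcodes, ub))
                clOfBc <- vector("list", length(ub))
                for (ci in seq_len(nc)) for (bi in bcOf[[ci]])
                    clOfBc[[bi]] <- c(clOfBc[[bi]], ci)
                ## min pairwise barcode ed per cluster pair (0 when they share one)
                minEd <- new.env(hash = TRUE)
                note <- function(ci, cj, e) {
                    if (ci == cj) return()
                    k <- if (ci < cj) paste(ci, cj) else paste(cj, ci)
                    cur <- minEd[[k]]
                    if (is.null(cur) || e < cur) minEd[[k]] <- e
                }
                for (bi in seq_along(ub)) {
                    cs <- unique(clOfBc[[bi]])
                    if (length(cs) > 1L)
                        for (x in seq_len(length(cs) - 1L))
                            for (y in (x + 1L):length(cs)) note(cs[x], cs[y], 0L)
                }
                if (nrow(bcPairs)) for (r in seq_len(nrow(bcPairs))) {
                    ci <- clOfBc[[bcPairs$i[r]]]; cj <- clOfBc[[bcPairs$j[r]]]
                    if (length(ci) && length(cj))
                        for (x in unique(ci)) for (y in unique(cj))
                            note(x, y, bcPairs$ed[r])
                }
                keys <- ls(minEd)
                if (!length(keys)) return(clusters)
                eds <- vapply(keys, function(k) minEd[[k]], integer(1))
                sel <- keys[eds == ed]
                if (!length(sel)) return(clusters)
                ij <- do.call(rbind, strsplit(sel, " "))
                ci <- as.integer(ij[, 1]); cj <- as.integer(ij[, 2])
                combSize <- vapply(clusters, `[[`, integer(1), "size")
                sz <- combSize[ci] + combSize[cj]
                consA <- vapply(clusters, `[[`, "", "cons")
                p1 <- pmin(consA[ci], consA[cj]); p2 <- pmax(consA[ci], consA[cj])
                mid <- vapply(clusters, `[[`, "", "minId")
                m1 <- pmin(mid[ci], mid[cj]); m2 <- pmax(mid[ci], mid[cj])
                ord <- order(-sz, p1, p2, m1, m2, method = "radix")
                accepted <- FALSE
                for (o in ord) {
                    a <- clusters[[ci[o]]]; b <- clusters[[cj[o]]]
                    res <- .evalMerge(a$members, b$members, ed, bc, vars,
                                      maxEd, jaccardMin, varQualMin)
                    auditRows[[length(auditRows) + 1L]] <<- data.frame(
                        ed = ed, cluster1 = a$cons, cluster2 = b$cons,
                        size1 = a$size, size2 = b$size,
                        accepted = res$accept, reason = res$reason,
                        stringsAsFactors = FALSE)
                    if (res$accept) {
                        merged <- newCluster(c(a$members, b$members))
                        clusters <- c(clusters[-c(ci[o], cj[o])], list(merged))
                        accepted <- TRUE
                        break
                    }
                }
                if (!accepted) return(clusters)
            }
        }
        for (ed in seq_len(maxEd)) clusters <- repeat_level(clusters, ed)
    }

    ## deterministic final order: size desc, consensus barcode, min read id
    ord <- order(-vapply(clusters, `[[`, integer(1), "size"),
                 vapply(clusters, `[[`, "", "cons"),
                 vapply(clusters, `[[`, "", "minId"), method = "radix")
    clusters <- clusters[ord]
    log <- if (length(auditRows)) do.call(rbind, auditRows) else
        data.frame(ed = integer(0), cluster1 = character(0),
                   cluster2 = character(0), size1 = integer(0),
                   size2 = integer(0), accepted = logical(0),
                   reason = character(0), stringsAsFactors = FALSE)
    methods::new("CloneClusterSet", clusters = clusters, reads = reads,
                 params = params, log = log)
}
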