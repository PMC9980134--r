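## Independent reference implementations used to verify the package's
## optimized code paths. These are deliberately naive (full DP matrices,
## quadratic pair scans) and share no code with the package internals.

## Unit-cost Levenshtein distance by full dynamic programming.
oracleEditDistance <- function(a, b) {
    A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
    m <- length(A); n <- length(B)
    D <- matrix(0L, m + 1L, n + 1L)
    D[, 1] <- 0:m; D[1, ] <- 0:n
    for (i in seq_len(m)) for (j in seq_len(n)) {
        D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                               D[i, j] + (A[i] != B[j]))
    }
    D[m + 1, n + 1]
}

## Optimal semi-global affine-gap alignment score (Gotoh): pattern global,
## subject ends free; N in either sequence matches at full match score.
## Gap of length L costs gapO + L * gapE.
oracleGotohScore <- function(pat, sub, match = 1, mismatch = -4,
                             gapO = 6, gapE = 1) {
    P <- strsplit(pat, "")[[1]]; S <- strsplit(sub, "")[[1]]
    m <- length(P); n <- length(S)
    NEG <- -1e9
    sc <- function(a, b) if (a == b || a == "N" || b == "N") match else mismatch
    ## M: P[i] aligned to S[j]; X: gap in subject (P[i] unmatched);
    ## Y: gap in pattern (S[j] unmatched, costs only interior)
    M <- X <- Y <- matrix(NEG, m + 1L, n + 1L)
    M[1, ] <- 0                          # free subject prefix
    for (i in seq_len(m)) X[i + 1, 1] <- -(gapO + i * gapE)
    for (i in seq_len(m)) {
        for (j in seq_len(n)) {
            best <- max(M[i, j], X[i, j], Y[i, j])
            M[i + 1, j + 1] <- best + sc(P[i], S[j])
            X[i + 1, j + 1] <- max(M[i, j + 1] - gapO - gapE,
                                   X[i, j + 1] - gapE)
            Y[i + 1, j + 1] <- max(M[i + 1, j] - gapO - gapE,
                                   Y[i + 1, j] - gapE)
        }
    }
    max(M[m + 1, ], X[m + 1, ])          # free subject suffix
}

## ---- brute-force clustering reference -------------------------------------
## Same algorithm semantics as clusterReads(), transcribed naively: no
## neighborhood index, all pairwise distances recomputed from scratch at
## every step, components by breadth-first search.

.oFilter <- function(varList, varQualMin) {
    rows <- NULL
    for (i in seq_along(varList)) {
        v <- varList[[i]]
        if (nrow(v)) rows <- rbind(rows, data.frame(
            key = paste0(v$pos, ":", v$ref, ">", v$alt), qual = v$qual,
            rd = i, stringsAsFactors = FALSE))
    }
    if (is.null(rows)) return(character(0))
    keys <- unique(rows$key)
    keep <- vapply(keys, function(k) {
        sup <- rows[rows$key == k, ]
        length(unique(sup$rd)) >= 2L || max(sup$qual) >= varQualMin
    }, logical(1))
    keys[keep]
}

.oJac <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    length(intersect(a, b)) / length(union(a, b))
}

.oSeed <- function(idx, varList, jaccardMin, varQualMin) {
    n <- length(idx)
    retained <- .oFilter(varList[idx], varQualMin)
    fs <- lapply(idx, function(i)
        intersect(unique(paste0(varList[[i]]$pos, ":", varList[[i]]$ref, ">",
                                varList[[i]]$alt)[seq_len(nrow(varList[[i]]))]),
                  retained))
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        adj[i, j] <- (!length(fs[[i]]) && !length(fs[[j]])) ||
            .oJac(fs[[i]], fs[[j]]) >= jaccardMin
    }
    seen <- rep(FALSE, n); comps <- list()
    for (s in seq_len(n)) {
        if (seen[s]) next
        queue <- s; seen[s] <- TRUE; comp <- integer(0)
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]; comp <- c(comp, v)
            nb <- which(adj[v, ] & !seen)
            seen[nb] <- TRUE; queue <- c(queue, nb)
        }
        comps[[length(comps) + 1L]] <- idx[sort(comp)]
    }
    comps
}

.oConsensus <- function(bcs, qtot) {
    cnt <- table(bcs)
    cand <- names(cnt)[cnt == max(cnt)]
    if (length(cand) > 1L) {
        tq <- vapply(cand, function(s) sum(qtot[bcs == s]), numeric(1))
        cand <- cand[tq == max(tq)]
    }
    sort(cand, method = "radix")[1]
}

## Full brute-force clustering; reads given as parallel vectors/lists.
## Returns the partition as a list of sorted readId character vectors,
## itself sorted, for order-free comparison.
oracleClusterLibrary <- function(readId, barcode, varList, qualTotal = NULL,
                                 maxEd = 2L, jaccardMin = 0.2,
                                 varQualMin = 50L) {
    if (is.null(qualTotal)) qualTotal <- rep(0, length(readId))
    clusters <- list()
    for (b in unique(barcode)) {
        idx <- which(barcode == b)
        clusters <- c(clusters, .oSeed(idx, varList, jaccardMin, varQualMin))
    }
    evalPair <- function(m1, m2, ed) {
        retained <- .oFilter(varList[c(m1, m2)], varQualMin)
        keysIn <- function(m) {
            k <- unlist(lapply(varList[m], function(v)
                if (nrow(v)) paste0(v$pos, ":", v$ref, ">", v$alt) else character(0)))
            intersect(unique(k), retained)
        }
        k1 <- keysIn(m1); k2 <- keysIn(m2)
        if (!((!length(k1) && !length(k2)) || .oJac(k1, k2) >= jaccardMin))
            return(FALSE)
        bcs <- unique(barcode[c(m1, m2)])
        if (length(bcs) > 1L) {
            for (x in seq_len(length(bcs) - 1L)) for (y in (x + 1L):length(bcs))
                if (oracleEditDistance(bcs[x], bcs[y]) > maxEd) return(FALSE)
        }
        abs(log2(length(m1) / length(m2))) > ed
    }
    if (maxEd >= 1L) for (ed in seq_len(maxEd)) {
        repeat {
            nc <- length(clusters)
            if (nc < 2L) break
            cand <- NULL
            for (x in seq_len(nc - 1L)) for (y in (x + 1L):nc) {
                b1 <- unique(barcode[clusters[[x]]])
                b2 <- unique(barcode[clusters[[y]]])
                d <- min(outer(b1, b2, Vectorize(oracleEditDistance)))
                if (d == ed)
                    cand <- rbind(cand, data.frame(x = x, y = y,
                        sz = length(clusters[[x]]) + length(clusters[[y]])))
            }
            if (is.null(cand)) break
            cons <- vapply(clusters, function(m)
                .oConsensus(barcode[m], qualTotal[m]), "")
            mid <- vapply(clusters, function(m) min(readId[m]), "")
            o <- order(-cand$sz,
                       pmin(cons[cand$x], cons[cand$y]),
                       pmax(cons[cand$x], cons[cand$y]),
                       pmin(mid[cand$x], mid[cand$y]),
                       pmax(mid[cand$x], mid[cand$y]), method = "radix")
            merged <- FALSE
            for (r in o) {
                if (evalPair(clusters[[cand$x[r]]], clusters[[cand$y[r]]], ed)) {
                    u <- sort(c(clusters[[cand$x[r]]], clusters[[cand$y[r]]]))
                    clusters <- c(clusters[-c(cand$x[r], cand$y[r])], list(u))
                    merged <- TRUE
                    break
                }
            }
            if (!merged) break
        }
    }
    parts <- lapply(clusters, function(m) sort(readId[m]))
    parts[order(vapply(parts, `[`, "", 1), method = "radix")]
}

## Partition of a CloneClusterSet in the same order-free form.
packagePartition <- function(cs) {
    d <- readData(cs@reads)
    parts <- lapply(cloneClusters(cs), function(cl) sort(d$readId[cl$members]))
    parts[order(vapply(parts, `[`, "", 1), method = "radix")]
}

## Mutate-and-translate oracle: apply one variant table to the ORF and
## translate the result with Biostrings.
oracleTranslateORF <- function(v, layout) {
    os <- IRanges::start(orfRange(layout)); oe <- IRanges::end(orfRange(layout))
    mutated <- applyVariants(as.character(referenceSeq(layout)), v)
    delta <- nchar(mutated) - length(referenceSeq(layout))
    orf <- substr(mutated, os, oe + delta)
    orf <- substr(orf, 1L, 3L * (nchar(orf) %/% 3L))
    ## plain code-table translation: no initiator special-casing, matching
    ## the per-codon consequence convention (an ATG>CTG change is missense)
    as.character(Biostrings::translate(Biostrings::DNAString(orf),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "X"))
}
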