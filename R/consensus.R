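## Per-clone consensus barcodes, final genotypes, protein consequences and
## homopolymer-context annotation.

#' Consensus barcode of a cluster
#'
#' The plurality (most frequent) member barcode string; ties are broken by
#' the highest summed per-base quality, then lexicographically. The result
#' is always one of the observed member barcodes.
#'
#' @param barcodes Character vector of member barcode strings.
#' @param quals Optional list of integer per-base quality vectors (same
#'   length); defaults to all-equal qualities.
#' @return The consensus barcode string.
#' @export
consensusBarcode <- function(barcodes, quals = NULL) {
    stopifnot(length(barcodes) >= 1L)
    qt <- if (is.null(quals)) rep(0L, length(barcodes)) else
        vapply(quals, sum, numeric(1))
    .plurality(barcodes, qt)
}

#' Final genotype of a cluster
#'
#' Applies the sequencing-error filter to the final cluster membership; an
#' empty result denotes a wild-type clone.
#'
#' @param variants List of the member reads' candidate-variant data.frames.
#' @param varQualMin Error-filter quality threshold (default Q50).
#' @return A candidate-variant data.frame.
#' @export
finalGenotype <- function(variants, varQualMin = 50L) {
    filterVariantErrors(variants, varQualMin)
}

.AA <- function(codon) {
    aa <- Biostrings::GENETIC_CODE[[codon]]
    if (is.null(aa)) "X" else aa
}

#' Translate nucleotide variants to protein consequences
#'
#' Variants inside the ORF are grouped by codon; substitutions hitting the
#' same codon are applied jointly. Each affected codon yields one label:
#' synonymous (`p.M1=`), missense (`p.M1I`), nonsense (`p.Q5Ter`); indels of
#' length not divisible by 3 yield a frameshift (`p.K3fs`), in-frame indels
#' `p.K3del`/`p.K3ins`. Variants outside the ORF are labelled non-coding.
#'
#' @param v A candidate-variant data.frame.
#' @param layout An [AmpliconLayout-class].
#' @return data.frame with columns `key`, `codon` (NA outside the ORF),
#'   `type` (synonymous/missense/nonsense/frameshift/inframe_del/
#'   inframe_ins/noncoding) and `label`.
#' @export
translateVariants <- function(v, layout) {
    refseq <- as.character(referenceSeq(layout))
    os <- IRanges::start(orfRange(layout)); oe <- IRanges::end(orfRange(layout))
    if (any(v$pos < 0L | v$pos > nchar(refseq)))
        stop("variant coordinates outside reference")
    out <- data.frame(key = character(0), codon = integer(0),
                      type = character(0), label = character(0),
                      stringsAsFactors = FALSE)
    if (nrow(v) == 0L) return(out)
    codonOf <- function(p) (p - os) %/% 3L + 1L
    refCodon <- function(ci) substr(refseq, os + 3L * (ci - 1L), os + 3L * ci - 1L)

    subRows <- v[v$vtype %in% c("SNV", "MNV"), , drop = FALSE]
    indelRows <- v[!(v$vtype %in% c("SNV", "MNV")), , drop = FALSE]

    ## expand substitutions to per-base changes inside the ORF
    baseChanges <- NULL
    ncRows <- list()
    if (nrow(subRows)) for (i in seq_len(nrow(subRows))) {
        p0 <- subRows$pos[i]; k <- nchar(subRows$ref[i])
        ps <- p0:(p0 + k - 1L)
        inOrf <- ps >= os & ps <= oe
        key <- paste0(subRows$pos[i], ":", subRows$ref[i], ">", subRows$alt[i])
        if (any(inOrf)) {
            baseChanges <- rbind(baseChanges, data.frame(
                pos = ps[inOrf],
                alt = strsplit(subRows$alt[i], "")[[1]][inOrf],
                key = key, stringsAsFactors = FALSE))
        }
        if (!any(inOrf))
            ncRows[[length(ncRows) + 1L]] <- data.frame(
                key = key, codon = NA_integer_, type = "noncoding",
                label = paste0("nc.", key), stringsAsFactors = FALSE)
    }
    codonRows <- list()
    if (!is.null(baseChanges)) {
        baseChanges$codon <- codonOf(baseChanges$pos)
        for (ci in sort(unique(baseChanges$codon))) {
            bc <- baseChanges[baseChanges$codon == ci, , drop = FALSE]
            rc <- refCodon(ci)
            ac <- strsplit(rc, "")[[1]]
            ac[bc$pos - (os + 3L * (ci - 1L)) + 1L] <- bc$alt
            ac <- paste(ac, collapse = "")
            refAA <- .AA(rc); altAA <- .AA(ac)
            type <- if (altAA == refAA) "synonymous"
                    else if (altAA == "*") "nonsense" else "missense"
            lab <- switch(type,
                synonymous = paste0("p.", refAA, ci, "="),
                nonsense = paste0("p.", refAA, ci, "Ter"),
                missense = paste0("p.", refAA, ci, altAA))
            codonRows[[length(codonRows) + 1L]] <- data.frame(
                key = paste(unique(bc$key), collapse = ";"), codon = ci,
                type = type, label = lab, stringsAsFactors = FALSE)
        }
    }
    indelOut <- list()
    if (nrow(indelRows)) for (i in seq_len(nrow(indelRows))) {
        key <- paste0(indelRows$pos[i], ":", indelRows$ref[i], ">",
                      indelRows$alt[i])
        if (indelRows$vtype[i] == "insertion") {
            p <- indelRows$pos[i]
            if (p >= os && p < oe) {
                len <- nchar(indelRows$alt[i])
                ci <- codonOf(p + 1L)
                refAA <- .AA(refCodon(ci))
                if (len %% 3L != 0L) {
                    indelOut[[length(indelOut) + 1L]] <- data.frame(
                        key = key, codon = ci, type = "frameshift",
                        label = paste0("p.", refAA, ci, "fs"),
                        stringsAsFactors = FALSE)
                } else {
                    indelOut[[length(indelOut) + 1L]] <- data.frame(
                        key = key, codon = ci, type = "inframe_ins",
                        label = paste0("p.", refAA, ci, "ins"),
                        stringsAsFactors = FALSE)
                }
            } else {
                indelOut[[length(indelOut) + 1L]] <- data.frame(
                    key = key, codon = NA_integer_, type = "noncoding",
                    label = paste0("nc.", key), stringsAsFactors = FALSE)
            }
        } else {                       # deletion
            p1 <- indelRows$pos[i]; p2 <- p1 + nchar(indelRows$ref[i]) - 1L
            lo <- max(p1, os); hi <- min(p2, oe)
            if (lo > hi) {
                indelOut[[length(indelOut) + 1L]] <- data.frame(
                    key = key, codon = NA_integer_, type = "noncoding",
                    label = paste0("nc.", key), stringsAsFactors = FALSE)
            } else {
                effLen <- hi - lo + 1L
                ci <- codonOf(lo)
                refAA <- .AA(refCodon(ci))
                if (effLen %% 3L != 0L) {
                    indelOut[[length(indelOut) + 1L]] <- data.frame(
                        key = key, codon = ci, type = "frameshift",
                        label = paste0("p.", refAA, ci, "fs"),
                        stringsAsFactors = FALSE)
                } else {
                    indelOut[[length(indelOut) + 1L]] <- data.frame(
                        key = key, codon = ci, type = "inframe_del",
                        label = paste0("p.", refAA, ci, "del"),
                        stringsAsFactors = FALSE)
                }
            }
        }
    }
    res <- do.call(rbind, c(codonRows, indelOut, ncRows))
    if (is.null(res)) return(out)
    res[order(is.na(res$codon), res$codon, res$key), , drop = FALSE]
}

#' Net reading-frame offset of a genotype
#'
#' Sum of ORF-overlapping indel length changes, modulo 3. Individual
#' frameshift events are reported per event by [translateVariants()]; this
#' gives the clone-level net frame (0 = net in-frame).
#'
#' @param v A candidate-variant data.frame.
#' @param layout An [AmpliconLayout-class].
#' @return Integer 0, 1 or 2.
#' @export
netFrameShift <- function(v, layout) {
    if (nrow(v) == 0L) return(0L)
    os <- IRanges::start(orfRange(layout)); oe <- IRanges::end(orfRange(layout))
    delta <- 0L
    for (i in seq_len(nrow(v))) {
        if (v$vtype[i] == "insertion") {
            if (v$pos[i] >= os && v$pos[i] < oe)
                delta <- delta + nchar(v$alt[i])
        } else if (v$vtype[i] == "deletion") {
            lo <- max(v$pos[i], os)
            hi <- min(v$pos[i] + nchar(v$ref[i]) - 1L, oe)
            if (lo <= hi) delta <- delta - (hi - lo + 1L)
        }
    }
    as.integer(delta %% 3L)
}

#' Flag frameshift indels at the 5' end of homopolymer runs
#'
#' TRUE for variants that are frameshift-length indels whose left-aligned
#' position equals the start of a homopolymer run (of the supplied minimum
#' length, default 4) or the position immediately preceding it. Such calls
#' are enriched for long-read sequencing artifacts.
#'
#' @param v A candidate-variant data.frame (indels left-aligned).
#' @param runs Homopolymer runs from [homopolymerRuns()].
#' @return Logical vector, one per variant row.
#' @export
annotateHomopolymerFrameshift <- function(v, runs) {
    if (nrow(v) == 0L) return(logical(0))
    isIndel <- v$vtype %in% c("insertion", "deletion")
    len <- abs(nchar(v$alt) - nchar(v$ref))
    isFs <- isIndel & (len %% 3L != 0L)
    vapply(seq_len(nrow(v)), function(i) {
        if (!isFs[i]) return(FALSE)
        any(v$pos[i] == runs$start | v$pos[i] == runs$start - 1L)
    }, logical(1))
}

#' Call consensus clones from a cluster set
#'
#' Derives per-region consensus barcodes, the error-filtered nucleotide
#' genotype, protein consequences and homopolymer annotation for every
#' cluster.
#'
#' @param cs A [CloneClusterSet-class].
#' @param homopolymerMin Minimum homopolymer run length for the frameshift
#'   context annotation (default 4).
#' @return A [CloneCalls-class].
#' @export
callClones <- function(cs, homopolymerMin = 4L) {
    reads <- cs@reads
    d <- readData(reads)
    layout <- layoutOf(reads)
    dual <- !is.null(d$barcode2)
    runs <- homopolymerRuns(referenceSeq(layout), homopolymerMin)
    runs <- runs[runs$base != "N", , drop = FALSE]   # barcode regions
    cls <- cloneClusters(cs)
    n <- length(cls)
    clusterId <- sprintf("clust%05d", seq_len(n))
    bc1 <- bc2 <- virt <- ntg <- aas <- character(n)
    nReads <- netf <- integer(n)
    hpfs <- logical(n)
    variants <- vector("list", n)
    for (i in seq_len(n)) {
        cl <- cls[[i]]
        m <- cl$members
        q1 <- lapply(d$bcQual1[m], function(q) as.integer(charToRaw(q)) - 33L)
        bc1[i] <- consensusBarcode(d$barcode1[m], q1)
        if (dual) {
            q2 <- lapply(d$bcQual2[m], function(q) as.integer(charToRaw(q)) - 33L)
            bc2[i] <- consensusBarcode(d$barcode2[m], q2)
            virt[i] <- paste0(bc1[i], bc2[i])
        } else virt[i] <- bc1[i]
        g <- cl$filt
        variants[[i]] <- g
        nReads[i] <- cl$size
        ntg[i] <- formatVariants(g)
        tr <- translateVariants(g, layout)
        aas[i] <- paste(tr$label, collapse = ",")
        netf[i] <- netFrameShift(g, layout)
        hpfs[i] <- any(annotateHomopolymerFrameshift(g, runs))
    }
    calls <- S4Vectors::DataFrame(clusterId = clusterId, barcode1 = bc1,
        virtualBarcode = virt, nReads = nReads, ntGenotype = ntg,
        aaConsequences = aas, netFrame = netf, homopolymerFs = hpfs,
        flags = rep("", n))
    calls$variants <- variants
    if (dual) calls$barcode2 <- bc2
    methods::new("CloneCalls", calls = calls, layout = layout)
}
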