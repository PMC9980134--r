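## Alignment and per-read extraction of barcodes and candidate variants.
##
## Reads are aligned semi-globally (read global, reference ends free) with
## affine gap penalties via Biostrings::pairwiseAlignment; degenerate N bases
## in the reference (the barcode regions) match any read base at full match
## score. Both orientations are tried and the better-scoring one kept.

.substitutionMatrix <- function(match = 1, mismatch = -4) {
    letters <- c("A", "C", "G", "T", "N")
    m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
    diag(m) <- match
    m["N", ] <- match
    m[, "N"] <- match
    m
}

#' Default alignment scoring parameters
#'
#' Match +1, mismatch -4, gap open -6, gap extend -1; reads scoring below
#' `scoreFloorFrac * read length` are flagged unalignable.
#' @return A named list of scoring parameters.
#' @export
alignmentScoring <- function() {
    list(match = 1, mismatch = -4, gapOpening = 6, gapExtension = 1,
         scoreFloorFrac = 0.25)
}

#' Align one read to the reference amplicon
#'
#' @param seq Read sequence (character or DNAString).
#' @param qual Integer vector of per-base Phred qualities (read orientation).
#' @param layout An [AmpliconLayout-class].
#' @param scoring List as from [alignmentScoring()].
#' @return A read-alignment object (list) with elements `read`, `qual`
#'   (reverse-complemented/reversed if the reverse orientation won), `pat`
#'   and `sub` (gapped aligned strings), `refOffset`, `score`, `orientation`
#'   ("+"/"-") and `ok` (FALSE when the score falls below the floor).
#' @export
alignRead <- function(seq, qual, layout, scoring = alignmentScoring()) {
    batchAlign(Biostrings::DNAStringSet(as.character(seq)), list(as.integer(qual)),
               layout, scoring)[[1]]
}

## Vectorized alignment of many reads; returns a list of read-alignment
## objects in input order.
batchAlign <- function(seqs, quals, layout, scoring = alignmentScoring()) {
    ref <- referenceSeq(layout)
    mat <- .substitutionMatrix(scoring$match, scoring$mismatch)
    doAln <- function(ss) Biostrings::pairwiseAlignment(
        ss, ref, type = "global-local", substitutionMatrix = mat,
        gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
    rcSet <- Biostrings::reverseComplement(seqs)
    fwd <- doAln(seqs)
    rev <- doAln(rcSet)
    sf <- Biostrings::score(fwd); sr <- Biostrings::score(rev)
    useRev <- sr > sf
    ## as.character on the aligned pattern/subject components gives the
    ## gapped strings directly; with a global pattern this equals
    ## alignedPattern()/alignedSubject() and is orders of magnitude faster
    unpack <- function(aln) list(
        pat = unname(as.character(Biostrings::pattern(aln))),
        sub = unname(as.character(Biostrings::subject(aln))),
        off = IRanges::start(Biostrings::subject(aln)))
    fa <- unpack(fwd); ra <- unpack(rev)
    fwdChar <- as.character(seqs); rcChar <- as.character(rcSet)
    lapply(seq_along(seqs), function(i) {
        rc <- useRev[i]
        a <- if (rc) list(pat = ra$pat[i], sub = ra$sub[i], off = ra$off[i])
             else list(pat = fa$pat[i], sub = fa$sub[i], off = fa$off[i])
        rd <- if (rc) rcChar[i] else fwdChar[i]
        q <- if (rc) base::rev(quals[[i]]) else quals[[i]]
        score <- if (rc) sr[i] else sf[i]
        list(read = rd, qual = q, pat = a$pat, sub = a$sub,
             refOffset = a$off - 1L, score = score,
             orientation = if (rc) "-" else "+",
             ok = score >= scoring$scoreFloorFrac * nchar(rd))
    })
}

## Column table of one alignment: per alignment column the type
## (M match, X mismatch, I insertion, D deletion), reference position
## (for I: the anchoring reference position, i.e. last consumed base) and
## read position (for D: last consumed read base, 0 if none).
alignmentColumns <- function(aln) {
    pch <- strsplit(aln$pat, "")[[1]]
    sch <- strsplit(aln$sub, "")[[1]]
    isP <- pch != "-"
    isS <- sch != "-"
    refPos <- aln$refOffset + cumsum(isS)
    readPos <- cumsum(isP)
    type <- ifelse(!isS, "I", ifelse(!isP, "D",
            ifelse(pch == sch | sch == "N" | pch == "N", "M", "X")))
    data.frame(type = type, refPos = refPos, readPos = readPos,
               readBase = pch, refBase = sch, stringsAsFactors = FALSE)
}

## Which columns fall inside a barcode region: consuming columns (M/X/D) by
## reference position; insertion columns only when anchored strictly inside
## (an insertion at a region boundary belongs to the non-barcode side).
.inRegion <- function(cols, s, e) {
    consuming <- cols$type != "I" & cols$refPos >= s & cols$refPos <= e
    inserted <- cols$type == "I" & cols$refPos >= s & cols$refPos <= (e - 1L)
    consuming | inserted
}

#' Extract barcode sequences and qualities from a read alignment
#'
#' @param aln A read-alignment object from [alignRead()].
#' @param layout An [AmpliconLayout-class].
#' @param stat Barcode quality summary: `"min"` (default, strictest) or
#'   `"mean"`.
#' @return List with `barcodes` (character per region), `quals` (list of
#'   integer vectors), `bcQual` (the summary statistic over all barcode
#'   bases), `ok`, and `reason` ("no_barcode" when a region is uncovered or
#'   entirely deleted).
#' @export
extractBarcodes <- function(aln, layout, stat = c("min", "mean")) {
    stat <- match.arg(stat)
    cols <- alignmentColumns(aln)
    br <- barcodeRegions(layout)
    covered <- range(cols$refPos[cols$type != "I"])
    barcodes <- character(length(br)); quals <- vector("list", length(br))
    for (i in seq_along(br)) {
        s <- IRanges::start(br)[i]; e <- IRanges::end(br)[i]
        if (covered[1] > s || covered[2] < e)
            return(list(barcodes = NULL, quals = NULL, bcQual = NA_integer_,
                        ok = FALSE, reason = "no_barcode"))
        sel <- .inRegion(cols, s, e) & cols$type != "D"
        if (!any(sel))
            return(list(barcodes = NULL, quals = NULL, bcQual = NA_integer_,
                        ok = FALSE, reason = "no_barcode"))
        bcChars <- cols$readBase[sel]
        bcQuals <- aln$qual[cols$readPos[sel]]
        ## canonicalize boundary indels into the degenerate region: an indel
        ## immediately flanking an N stretch is score-equivalent to the same
        ## indel inside it, and the aligner parks it outside
        insAfter <- cols$type == "I" & cols$refPos == e
        if (any(insAfter)) {
            bcChars <- c(bcChars, cols$readBase[insAfter])
            bcQuals <- c(bcQuals, aln$qual[cols$readPos[insAfter]])
        }
        insBefore <- cols$type == "I" & cols$refPos == s - 1L
        if (any(insBefore)) {
            bcChars <- c(cols$readBase[insBefore], bcChars)
            bcQuals <- c(aln$qual[cols$readPos[insBefore]], bcQuals)
        }
        dcols <- which(cols$type == "D" & cols$refPos > e)
        if (length(dcols)) {
            ## first deletion run right of the region; if its left-aligned
            ## position abuts the region end, the gap belongs to the region
            ## and flank bases were pulled into it: trim them off
            k <- 1L
            while (k < length(dcols) && dcols[k + 1L] == dcols[k] + 1L)
                k <- k + 1L
            p <- cols$refPos[dcols[1]]
            refseq <- as.character(referenceSeq(layout))
            la <- leftAlignVariant(p, substr(refseq, p, p + k - 1L), "", refseq)
            if (la$pos <= e + 1L && p - e <= length(bcChars)) {
                keep <- seq_len(max(0L, length(bcChars) - k))
                bcChars <- bcChars[keep]; bcQuals <- bcQuals[keep]
            }
        }
        if (!length(bcChars))
            return(list(barcodes = NULL, quals = NULL, bcQual = NA_integer_,
                        ok = FALSE, reason = "no_barcode"))
        barcodes[i] <- paste(bcChars, collapse = "")
        quals[[i]] <- bcQuals
    }
    allq <- unlist(quals)
    bcq <- if (stat == "min") min(allq) else as.integer(floor(mean(allq)))
    list(barcodes = barcodes, quals = quals, bcQual = bcq, ok = TRUE, reason = "")
}

#' Barcode-quality read filter
#'
#' Reads whose barcode quality falls below the threshold are dropped; such
#' reads often come from multi-occupancy sequencing wells. The default Q62
#' threshold keeps a read at exactly Q62.
#'
#' @param minBcQual The read's barcode quality statistic.
#' @param minQual Threshold (default 62).
#' @return TRUE to keep, FALSE to drop.
#' @export
filterBarcodeQuality <- function(minBcQual, minQual = 62L) {
    !is.na(minBcQual) & minBcQual >= minQual
}

#' Extract candidate variants from a read alignment
#'
#' Every mismatch or gap outside the barcode regions becomes a candidate
#' variant. Adjacent alignment columns of the same type merge into one event
#' (MNV / multi-base indel); indels are left-aligned against the reference.
#' Qualities: SNV/MNV take the (minimum) alt basecall quality. An indel has
#' no basecall of its own and its placement within a homopolymer run is
#' ambiguous, so its quality is the minimum read quality over the event's
#' ambiguity span: the inserted bases (insertions) or the gap's flanking
#' read bases (deletions), extended across adjacent read bases that equal
#' the event's terminal bases (the run of equivalent gap placements), plus
#' one further flanking base on each side.
#'
#' @param aln A read-alignment object from [alignRead()].
#' @param layout An [AmpliconLayout-class].
#' @return A candidate-variant data.frame (zero rows for a perfect read).
#' @export
extractVariants <- function(aln, layout) {
    cols <- alignmentColumns(aln)
    br <- barcodeRegions(layout)
    inBc <- rep(FALSE, nrow(cols))
    for (i in seq_along(br))
        inBc <- inBc | .inRegion(cols, IRanges::start(br)[i], IRanges::end(br)[i])
    idx <- which(cols$type != "M" & !inBc)
    if (!length(idx)) return(emptyVariants())
    ## split into runs of adjacent columns with identical type
    brk <- c(TRUE, diff(idx) != 1L | cols$type[idx[-1]] != cols$type[idx[-length(idx)]])
    runId <- cumsum(brk)
    pos <- ref <- alt <- vt <- character(0); qual <- integer(0)
    events <- split(idx, runId)
    n <- length(events)
    pos <- integer(n); ref <- alt <- vt <- character(n); qual <- integer(n)
    readLen <- nchar(aln$read)
    rdChars <- strsplit(aln$read, "")[[1]]
    ## min read quality over an indel's ambiguity span: [a, b] extended
    ## across the maximal equal-base read runs at its boundaries (the set of
    ## score-equivalent gap placements), plus one flanking base on each side
    spanQual <- function(a, b) {
        l <- max(a, 1L); r <- min(b, readLen)
        while (l - 1L >= 1L && rdChars[l - 1L] == rdChars[l]) l <- l - 1L
        while (r + 1L <= readLen && rdChars[r + 1L] == rdChars[r]) r <- r + 1L
        span <- max(1L, l - 1L):min(readLen, r + 1L)
        min(aln$qual[span])
    }
    for (k in seq_len(n)) {
        ii <- events[[k]]
        ty <- cols$type[ii[1]]
        if (ty == "X") {
            pos[k] <- cols$refPos[ii[1]]
            ref[k] <- paste(cols$refBase[ii], collapse = "")
            alt[k] <- paste(cols$readBase[ii], collapse = "")
            vt[k] <- if (length(ii) == 1L) "SNV" else "MNV"
            qual[k] <- min(aln$qual[cols$readPos[ii]])
            if (length(ii) >= 2L) {
                ## multi-base substitutions are usually re-representations
                ## of an indel-containing region; widen slightly
                rp <- range(cols$readPos[ii])
                span <- max(1L, rp[1] - 2L):min(readLen, rp[2] + 2L)
                qual[k] <- min(qual[k], aln$qual[span])
            }
            ## a mismatch at the very start/end of the alignment is
            ## interchangeable with an indel against the free subject end;
            ## fold nearby basecall confidence into its quality
            if (ii[1] <= 2L || ii[length(ii)] >= nrow(cols) - 1L) {
                rp <- range(cols$readPos[ii])
                span <- max(1L, rp[1] - 4L):min(readLen, rp[2] + 4L)
                qual[k] <- min(qual[k], aln$qual[span])
            }
        } else if (ty == "I") {
            pos[k] <- cols$refPos[ii[1]]
            ref[k] <- ""
            alt[k] <- paste(cols$readBase[ii], collapse = "")
            vt[k] <- "insertion"
            rp <- cols$readPos[ii]
            qual[k] <- spanQual(min(rp), max(rp))
        } else {
            pos[k] <- cols$refPos[ii[1]]
            ref[k] <- paste(cols$refBase[ii], collapse = "")
            alt[k] <- ""
            vt[k] <- "deletion"
            left <- cols$readPos[ii[1]]
            qual[k] <- spanQual(left, left + 1L)
        }
    }
    ## difference events separated by at most two matching columns form one
    ## ambiguity group: such composites typically re-encode a single error
    ## plus a true variant, so every member is capped by the group minimum
    ## quality over the group read span (+/- 2 bases)
    if (n >= 2L) {
        starts <- vapply(events, `[`, integer(1), 1L)
        ends <- vapply(events, function(e) e[length(e)], integer(1))
        grp <- cumsum(c(TRUE, starts[-1] - ends[-n] - 1L > 2L))
        for (g in unique(grp)) {
            mem <- which(grp == g)
            if (length(mem) < 2L) next
            ## for D columns readPos is the left-flank read base
            rp <- range(unlist(lapply(events[mem], function(e) cols$readPos[e])))
            span <- max(1L, rp[1] - 2L):min(readLen, max(rp[2] + 2L, 1L))
            gq <- min(aln$qual[span])
            qual[mem] <- pmin(qual[mem], gq)
        }
    }
    v <- variantTable(pos, ref, alt, qual, vt)
    v <- leftAlignVariants(v, as.character(referenceSeq(layout)))
    ## an indel abutting a degenerate barcode region is indistinguishable
    ## from an indel inside the region (N matches any base, so the gap
    ## placements tie); assign such events to the barcode side, i.e. drop
    ## them from the candidate variants
    if (nrow(v)) {
        drop <- rep(FALSE, nrow(v))
        for (i in seq_along(br)) {
            s <- IRanges::start(br)[i]; e <- IRanges::end(br)[i]
            isIns <- v$vtype == "insertion"
            isDel <- v$vtype == "deletion"
            drop <- drop |
                (isIns & (v$pos == e | v$pos == s - 1L)) |
                (isDel & (v$pos == e + 1L |
                          v$pos + nchar(v$ref) - 1L == s - 1L))
        }
        v <- v[!drop, , drop = FALSE]
    }
    v
}

#' Extract barcodes and variants for a set of reads
#'
#' Runs alignment, barcode extraction, the barcode-quality filter and
#' candidate-variant extraction over a FASTQ file (or in-memory reads).
#'
#' @param fastq Path to a FASTQ file (Phred+33), or a named
#'   [Biostrings::QualityScaledDNAStringSet].
#' @param layout An [AmpliconLayout-class].
#' @param minBcQual Barcode quality threshold (default Q62).
#' @param bcQualStat `"min"` or `"mean"` summary over barcode bases.
#' @param scoring Alignment scoring, see [alignmentScoring()].
#' @param nWorkers Parallel workers for the alignment/extraction step
#'   (forked; results are order-stable so the worker count never changes
#'   results).
#' @return A [ReadExtractions-class]; dropped reads are retained with
#'   `keep = FALSE` and a `dropReason`.
#' @export
extractReads <- function(fastq, layout, minBcQual = 62L,
                         bcQualStat = c("min", "mean"),
                         scoring = alignmentScoring(), nWorkers = 1L) {
    bcQualStat <- match.arg(bcQualStat)
    if (is.character(fastq)) {
        seqs <- Biostrings::readDNAStringSet(fastq, format = "fastq",
                                             with.qualities = TRUE)
        qstr <- as.character(S4Vectors::mcols(seqs)$qualities)
    } else {
        qstr <- as.character(Biostrings::quality(fastq))
        seqs <- Biostrings::DNAStringSet(as.character(fastq))
    }
    ids <- sub("\\s.*$", "", names(seqs))
    S4Vectors::mcols(seqs) <- NULL
    n <- length(seqs)
    params <- list(minBcQual = minBcQual, bcQualStat = bcQualStat,
                   scoring = scoring)
    nbr <- length(barcodeRegions(layout))
    if (n == 0L) {
        df <- S4Vectors::DataFrame(readId = character(0), barcode1 = character(0),
            bcQual1 = character(0), virtualBarcode = character(0),
            minBcQual = integer(0), isWT = logical(0), keep = logical(0),
            dropReason = character(0))
        df$variants <- list()
        if (nbr == 2L) { df$barcode2 <- character(0); df$bcQual2 <- character(0) }
        return(methods::new("ReadExtractions", data = df, layout = layout,
                            params = params))
    }
    quals <- lapply(qstr, function(q) as.integer(charToRaw(q)) - 33L)

    oneChunk <- function(idx) {
        alns <- batchAlign(seqs[idx], quals[idx], layout, scoring)
        lapply(seq_along(idx), function(j) {
            a <- alns[[j]]
            if (!a$ok)
                return(list(bc = rep(NA_character_, nbr),
                            bq = rep(NA_character_, nbr), mq = NA_integer_,
                            variants = emptyVariants(), keep = FALSE,
                            reason = "unaligned"))
            bx <- extractBarcodes(a, layout, bcQualStat)
            if (!bx$ok)
                return(list(bc = rep(NA_character_, nbr),
                            bq = rep(NA_character_, nbr), mq = NA_integer_,
                            variants = emptyVariants(), keep = FALSE,
                            reason = bx$reason))
            keep <- filterBarcodeQuality(bx$bcQual, minBcQual)
            list(bc = bx$barcodes,
                 bq = vapply(bx$quals, intToPhred, ""),
                 mq = bx$bcQual,
                 variants = extractVariants(a, layout),
                 keep = keep,
                 reason = if (keep) "" else "low_bc_qual")
        })
    }
    chunks <- if (nWorkers > 1L) {
        unname(split(seq_len(n), cut(seq_len(n), nWorkers, labels = FALSE)))
    } else list(seq_len(n))
    resChunks <- if (nWorkers > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(chunks, oneChunk, mc.cores = nWorkers)
    } else lapply(chunks, oneChunk)
    res <- unname(do.call(c, resChunks))

    bc1 <- vapply(res, function(r) r$bc[1], "")
    bq1 <- vapply(res, function(r) r$bq[1], "")
    variants <- lapply(res, `[[`, "variants")
    df <- S4Vectors::DataFrame(
        readId = ids, barcode1 = bc1, bcQual1 = bq1,
        virtualBarcode = NA_character_,
        minBcQual = vapply(res, function(r) r$mq, integer(1)),
        isWT = vapply(variants, nrow, integer(1)) == 0L,
        keep = vapply(res, function(r) r$keep, logical(1)),
        dropReason = vapply(res, function(r) r$reason, ""))
    df$variants <- variants
    if (nbr == 2L) {
        df$barcode2 <- vapply(res, function(r) r$bc[2], "")
        df$bcQual2 <- vapply(res, function(r) r$bq[2], "")
        df$virtualBarcode <- paste0(df$barcode1, df$barcode2)
    } else {
        df$virtualBarcode <- df$barcode1
    }
    df$virtualBarcode[!df$keep & is.na(df$barcode1)] <- NA_character_
    methods::new("ReadExtractions", data = df, layout = layout, params = params)
}
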