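## Barcode-uniqueness classification and PCR-crossover chimera detection.

#' Classify barcode uniqueness across called clones
#'
#' Groups clones by a key barcode. A group with a single clone is `unique`;
#' a multi-clone group is `non_unique_remediable` when the dominant clone
#' holds strictly more than two thirds of the group's reads (its readout
#' would still be dominated by one genotype), otherwise `non_unique`.
#'
#' @param calls A [CloneCalls-class].
#' @param key `"virtual"` (default) or `"upstream"`: which barcode defines a
#'   group. Upstream keying reproduces the analysis one would get without
#'   virtual barcodes.
#' @return data.frame with one row per barcode group: `barcode`, `status`,
#'   `nClones`, `readCounts` (comma-joined), `dominantShare`.
#' @export
classifyBarcodeUniqueness <- function(calls, key = c("virtual", "upstream")) {
    key <- match.arg(key)
    d <- callsTable(calls)
    kb <- if (key == "virtual") d$virtualBarcode else d$barcode1
    groups <- split(seq_len(nrow(d)), kb)
    res <- lapply(names(groups), function(b) {
        idx <- groups[[b]]
        counts <- sort(d$nReads[idx], decreasing = TRUE)
        status <- if (length(idx) == 1L) "unique"
            else if (max(counts) > (2 / 3) * sum(counts)) "non_unique_remediable"
            else "non_unique"
        data.frame(barcode = b, status = status, nClones = length(idx),
                   readCounts = paste(counts, collapse = ","),
                   dominantShare = max(counts) / sum(counts),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    if (is.null(out)) out <- data.frame(barcode = character(0),
        status = character(0), nClones = integer(0),
        readCounts = character(0), dominantShare = numeric(0))
    out[order(out$barcode, method = "radix"), , drop = FALSE]
}

## Genotype overlap between two clones' variant key sets:
## "complete" (identical, non-empty), "partial" (non-empty intersection),
## "wt_only" (both wild-type), or NA (no overlap).
.overlapType <- function(ka, kb) {
    if (length(ka) == 0L && length(kb) == 0L) return("wt_only")
    if (length(ka) && length(kb) && setequal(ka, kb)) return("complete")
    if (length(intersect(ka, kb)) > 0L) return("partial")
    NA_character_
}

#' Detect putative PCR-crossover chimeras via dual barcodes
#'
#' A crossover molecule shares its upstream barcode with one parent clone
#' and its downstream barcode with the other. Within groups of clones whose
#' anchor-flank barcodes are identical, a pair is chimera evidence when
#' their genotypes overlap (identical sets, non-empty intersection, or both
#' wild-type) while their other-flank barcodes are entirely different
#' (edit distance greater than `maxEd`, so barcodes that clustering could
#' conflate are never called different). Chimera sets are maximal under the
#' transitive closure of this pairwise relation.
#'
#' @param calls A [CloneCalls-class]; the layout must have two barcode
#'   regions.
#' @param maxEd The merge edit-distance limit (default 2).
#' @param direction `"both"` (default) anchors on each flank in turn;
#'   `"upstream"`/`"downstream"` anchor on one flank only. Upstream-only is
#'   the classical dual-barcode analysis.
#' @return data.frame with one row per (set, member): `setId`, `direction`,
#'   `anchorBarcode`, `clusterId`, `otherBarcode`, `evidence` (strongest
#'   pairwise overlap in the set: complete > partial > wt_only).
#' @export
detectChimeras <- function(calls, maxEd = 2L,
                           direction = c("both", "upstream", "downstream")) {
    direction <- match.arg(direction)
    d <- callsTable(calls)
    if (is.null(d$barcode2))
        stop("chimera detection requires a dual-barcode layout")
    keys <- lapply(d$variants, variantKey)
    dirs <- if (direction == "both") c("upstream", "downstream") else direction
    rows <- list()
    setCount <- 0L
    for (dir in dirs) {
        anchor <- if (dir == "upstream") d$barcode1 else d$barcode2
        other <- if (dir == "upstream") d$barcode2 else d$barcode1
        for (b in sort(unique(anchor), method = "radix")) {
            idx <- which(anchor == b)
            if (length(idx) < 2L) next
            edges <- NULL
            ev <- character(0)
            for (x in seq_len(length(idx) - 1L)) for (y in (x + 1L):length(idx)) {
                i <- idx[x]; j <- idx[y]
                if (as.integer(utils::adist(other[i], other[j])) <= maxEd) next
                ov <- .overlapType(keys[[i]], keys[[j]])
                if (is.na(ov)) next
                edges <- rbind(edges, c(x, y))
                ev <- c(ev, ov)
            }
            if (is.null(edges)) next
            comp <- unionFindComponents(length(idx), edges)
            for (cid in unique(comp)) {
                mem <- which(comp == cid)
                if (length(mem) < 2L) next
                inSet <- edges[, 1] %in% mem
                strength <- c("complete" = 3L, "partial" = 2L, "wt_only" = 1L)
                best <- names(which.max(strength[unique(ev[inSet])]))
                setCount <- setCount + 1L
                rows[[length(rows) + 1L]] <- data.frame(
                    setId = setCount, direction = dir, anchorBarcode = b,
                    clusterId = d$clusterId[idx[mem]],
                    otherBarcode = other[idx[mem]], evidence = best,
                    stringsAsFactors = FALSE)
            }
        }
    }
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(setId = integer(0),
        direction = character(0), anchorBarcode = character(0),
        clusterId = character(0), otherBarcode = character(0),
        evidence = character(0), stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Apply QC flags to clone calls
#'
#' Adds `non_unique`/`remediable` (from [classifyBarcodeUniqueness()]) and
#' `chimera_suspect` (from [detectChimeras()]) to the calls' `flags` column.
#'
#' @param calls A [CloneCalls-class].
#' @param uniqueness Output of [classifyBarcodeUniqueness()] (virtual key).
#' @param chimeras Output of [detectChimeras()], or NULL.
#' @return The updated [CloneCalls-class].
#' @export
flagCloneCalls <- function(calls, uniqueness, chimeras = NULL) {
    d <- callsTable(calls)
    status <- uniqueness$status[match(d$virtualBarcode, uniqueness$barcode)]
    flags <- lapply(seq_len(nrow(d)), function(i) {
        f <- character(0)
        if (!is.na(status[i]) && status[i] != "unique") {
            f <- c(f, "non_unique")
            if (status[i] == "non_unique_remediable") f <- c(f, "remediable")
        }
        if (!is.null(chimeras) && d$clusterId[i] %in% chimeras$clusterId)
            f <- c(f, "chimera_suspect")
        f
    })
    d$flags <- vapply(flags, paste, "", collapse = ",")
    methods::initialize(calls, calls = d)
}

#' Cross-tabulate chimera involvement against non-uniqueness
#'
#' For each upstream barcode, tabulates whether it is involved in an
#' upstream-anchored chimera set (detected with virtual barcodes) against
#' whether it is non-unique without virtual barcodes, and reports the
#' conditional rates.
#'
#' @param calls A [CloneCalls-class] from a virtual-barcode run
#'   (dual-barcode layout).
#' @param callsUpstream Optionally, a [CloneCalls-class] from a re-run with
#'   virtual barcodes disabled (clustering keyed on the upstream barcode
#'   alone); this is the faithful "virtual off" comparison. When omitted,
#'   uniqueness is approximated by re-keying `calls` on the upstream
#'   barcode.
#' @param maxEd Merge edit-distance limit used for "entirely different".
#' @return List with `table` (2x2 contingency of upstream barcodes),
#'   `pChimeraGivenNonUnique`, `pUniqueGivenNoChimera`,
#'   `pNonUniqueGivenChimera`.
#' @export
crossTabulateChimeraFlags <- function(calls, callsUpstream = NULL, maxEd = 2L) {
    chim <- detectChimeras(calls, maxEd = maxEd, direction = "upstream")
    uniq <- classifyBarcodeUniqueness(
        if (is.null(callsUpstream)) calls else callsUpstream, key = "upstream")
    allBc <- uniq$barcode
    chimFlag <- allBc %in% chim$anchorBarcode
    nonUnique <- uniq$status != "unique"
    tab <- table(chimera = factor(chimFlag, c(FALSE, TRUE)),
                 non_unique = factor(nonUnique, c(FALSE, TRUE)))
    rate <- function(num, den) if (den == 0L) NA_real_ else num / den
    list(table = tab,
         pChimeraGivenNonUnique = rate(sum(chimFlag & nonUnique), sum(nonUnique)),
         pUniqueGivenNoChimera = rate(sum(!chimFlag & !nonUnique), sum(!chimFlag)),
         pNonUniqueGivenChimera = rate(sum(chimFlag & nonUnique), sum(chimFlag)))
}
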