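#' @include AmpliconLayout-class.R
NULL

#' ReadExtractions: per-read barcodes, candidate variants and qualities
#'
#' One row per input read. Columns of the backing DataFrame:
#' `readId`, `barcode1`/`bcQual1` (and `barcode2`/`bcQual2` for dual-barcode
#' layouts; qualities are Phred+33 strings), `virtualBarcode` (upstream and
#' downstream barcodes concatenated in reference order), `minBcQual`,
#' `variants` (list column of candidate-variant data.frames), `isWT`,
#' `keep` and `dropReason` ("" | "unaligned" | "no_barcode" | "low_bc_qual").
#'
#' @slot data A [S4Vectors::DataFrame] as described above.
#' @slot layout The [AmpliconLayout-class] the reads were extracted against.
#' @slot params List of extraction parameters actually used.
#' @export
setClass("ReadExtractions",
    representation(data = "DataFrame", layout = "AmpliconLayout",
                   params = "list"))

setValidity("ReadExtractions", function(object) {
    need <- c("readId", "barcode1", "bcQual1", "virtualBarcode",
              "minBcQual", "variants", "isWT", "keep", "dropReason")
    miss <- setdiff(need, colnames(object@data))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    if (anyDuplicated(object@data$readId)) return("duplicated read ids")
    wt <- vapply(object@data$variants, nrow, integer(1)) == 0L
    if (!identical(unname(wt), unname(object@data$isWT)))
        return("isWT inconsistent with variants")
    TRUE
})

#' Construct a ReadExtractions set directly
#'
#' Mainly useful for tests and for clustering experiments that do not start
#' from FASTQ: builds the container from plain vectors.
#'
#' @param readId Character vector of unique read ids.
#' @param barcode1 Upstream (or only) barcode sequences.
#' @param variants List of candidate-variant data.frames, one per read.
#' @param barcode2 Downstream barcodes, or NULL for single-barcode layouts.
#' @param bcQual1,bcQual2 Phred+33 quality strings for the barcodes; default
#'   assumes maximal quality.
#' @param minBcQual Integer minimum barcode quality per read.
#' @param keep Logical; reads failing upstream filters carry FALSE.
#' @param dropReason Character; "" for kept reads.
#' @param layout An [AmpliconLayout-class]; a minimal placeholder is built
#'   when omitted.
#' @param params List of parameters to record.
#' @return A [ReadExtractions-class].
#' @export
readSet <- function(readId, barcode1, variants, barcode2 = NULL,
                    bcQual1 = NULL, bcQual2 = NULL, minBcQual = NULL,
                    keep = NULL, dropReason = NULL, layout = NULL,
                    params = list()) {
    n <- length(readId)
    if (is.null(bcQual1)) bcQual1 <- vapply(nchar(barcode1), function(k)
        intToPhred(rep(93L, k)), "")
    if (!is.null(barcode2) && is.null(bcQual2)) bcQual2 <- vapply(nchar(barcode2),
        function(k) intToPhred(rep(93L, k)), "")
    if (is.null(minBcQual)) minBcQual <- rep(93L, n)
    if (is.null(keep)) keep <- rep(TRUE, n)
    if (is.null(dropReason)) dropReason <- rep("", n)
    virt <- if (is.null(barcode2)) barcode1 else paste0(barcode1, barcode2)
    df <- S4Vectors::DataFrame(
        readId = as.character(readId), barcode1 = as.character(barcode1),
        bcQual1 = as.character(bcQual1), virtualBarcode = virt,
        minBcQual = as.integer(minBcQual),
        isWT = vapply(variants, nrow, integer(1)) == 0L,
        keep = keep, dropReason = dropReason)
    df$variants <- variants
    if (!is.null(barcode2)) {
        df$barcode2 <- as.character(barcode2)
        df$bcQual2 <- as.character(bcQual2)
    }
    if (is.null(layout)) {
        bl <- max(nchar(barcode1), 1L)
        refSeq <- paste0(strrep("N", bl), "ATGTAA")
        layout <- suppressWarnings(
            ampliconLayout(refSeq, c(bl + 1L, bl + 6L), list(c(1L, bl))))
    }
    methods::new("ReadExtractions", data = df, layout = layout, params = params)
}

#' @describeIn ReadExtractions-class Number of reads (kept + dropped).
#' @param x,object A ReadExtractions.
#' @export
setMethod("length", "ReadExtractions", function(x) nrow(x@data))

#' @describeIn ReadExtractions-class The backing DataFrame.
#' @export
setGeneric("readData", function(x) standardGeneric("readData"))

#' @export
setMethod("readData", "ReadExtractions", function(x) x@data)

#' @describeIn ReadExtractions-class Layout used for extraction.
#' @export
setGeneric("layoutOf", function(x) standardGeneric("layoutOf"))

#' @export
setMethod("layoutOf", "ReadExtractions", function(x) x@layout)

setMethod("show", "ReadExtractions", function(object) {
    d <- object@data
    cat("ReadExtractions: ", nrow(d), " reads (", sum(d$keep), " kept)\n", sep = "")
    if (nrow(d)) {
        drop <- table(d$dropReason[!d$keep])
        for (r in names(drop))
            cat("  dropped ", drop[[r]], " (", r, ")\n", sep = "")
        cat("  WT among kept: ", sum(d$isWT & d$keep), "\n", sep = "")
    }
})

#' Write the extractions table
#'
#' @param x A [ReadExtractions-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeExtractions <- function(x, path) {
    d <- x@data
    out <- data.frame(read_id = d$readId, barcode1 = d$barcode1,
                      stringsAsFactors = FALSE)
    if (!is.null(d$barcode2)) out$barcode2 <- d$barcode2
    out$virtual_barcode <- d$virtualBarcode
    out$min_bc_qual <- d$minBcQual
    out$variants <- vapply(d$variants, formatVariants, "")
    out$keep <- d$keep
    out$drop_reason <- d$dropReason
    utils::write.table(out[order(out$read_id), ], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
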