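#' AmpliconLayout: reference amplicon, ORF and barcode regions
#'
#' Describes the sequencing template: the reference sequence, the coordinates
#' of the open reading frame, and one or two degenerate barcode regions. All
#' coordinates are 1-based inclusive. With two barcode regions the first (by
#' reference position) is the "upstream" and the second the "downstream"
#' barcode.
#'
#' @slot refSeq A [Biostrings::DNAString] reference; barcode regions are
#'   degenerate (N) stretches.
#' @slot orf An [IRanges::IRanges] of length 1 with the ORF coordinates.
#' @slot barcodeRegions An [IRanges::IRanges] with 1 or 2 barcode intervals,
#'   ordered by start.
#' @slot name Label for the amplicon.
#'
#' @export
setClass("AmpliconLayout",
    representation(refSeq = "DNAString", orf = "IRanges",
                   barcodeRegions = "IRanges", name = "character"))

setValidity("AmpliconLayout", function(object) {
    msg <- character(0)
    L <- length(object@refSeq)
    br <- object@barcodeRegions
    if (length(br) < 1L || length(br) > 2L)
        msg <- c(msg, "need 1 or 2 barcode regions")
    if (length(object@orf) != 1L)
        msg <- c(msg, "need exactly one ORF interval")
    rng <- c(br, object@orf)
    if (any(IRanges::start(rng) < 1L) || any(IRanges::end(rng) > L))
        msg <- c(msg, "interval outside reference")
    if (length(br) == 2L && IRanges::start(br)[2] <= IRanges::end(br)[1])
        msg <- c(msg, "barcode regions overlap or are unordered")
    ## bases outside barcode regions must be ACGT
    chars <- strsplit(as.character(object@refSeq), "")[[1]]
    inside <- rep(FALSE, L)
    for (i in seq_along(br))
        inside[IRanges::start(br)[i]:IRanges::end(br)[i]] <- TRUE
    if (any(!chars[!inside] %in% c("A", "C", "G", "T")))
        msg <- c(msg, "non-ACGT base outside barcode regions")
    if (length(msg)) msg else TRUE
})

#' Construct an AmpliconLayout
#'
#' @param refSeq Reference sequence (character or DNAString); barcode
#'   regions should be N stretches.
#' @param orf Numeric `c(start, end)` of the ORF, 1-based inclusive.
#' @param barcodeRegions List of numeric `c(start, end)` pairs (1 or 2),
#'   1-based inclusive.
#' @param name Amplicon label.
#' @return A validated [AmpliconLayout-class] object. An ORF whose length is
#'   not a multiple of 3, or that does not begin with ATG, triggers a warning
#'   (not an error). Non-degenerate bases inside a barcode region also warn.
#' @export
ampliconLayout <- function(refSeq, orf, barcodeRegions, name = "amplicon") {
    refSeq <- Biostrings::DNAString(as.character(refSeq))
    br <- do.call(rbind, lapply(barcodeRegions, function(x) as.integer(x[1:2])))
    br <- br[order(br[, 1]), , drop = FALSE]
    ## overlap among regions is a hard error
    if (nrow(br) == 2L && br[2, 1] <= br[1, 2])
        stop("layout error: barcode regions overlap")
    obj <- methods::new("AmpliconLayout", refSeq = refSeq,
        orf = IRanges::IRanges(as.integer(orf[1]), as.integer(orf[2])),
        barcodeRegions = IRanges::IRanges(br[, 1], br[, 2]),
        name = as.character(name))
    w <- IRanges::width(obj@orf)
    if (w %% 3L != 0L)
        warning("ORF length ", w, " is not a multiple of 3")
    else if (as.character(Biostrings::subseq(refSeq, orf[1], orf[1] + 2L)) != "ATG")
        warning("ORF does not begin with a start codon")
    for (i in seq_len(nrow(br))) {
        reg <- as.character(Biostrings::subseq(refSeq, br[i, 1], br[i, 2]))
        if (grepl("[^N]", reg))
            warning("barcode region ", i, " contains non-degenerate bases")
    }
    obj
}

#' @describeIn AmpliconLayout-class Reference sequence as a DNAString.
#' @param object,x An AmpliconLayout.
#' @export
setGeneric("referenceSeq", function(x) standardGeneric("referenceSeq"))

#' @export
setMethod("referenceSeq", "AmpliconLayout", function(x) x@refSeq)

#' @describeIn AmpliconLayout-class ORF interval.
#' @export
setGeneric("orfRange", function(x) standardGeneric("orfRange"))

#' @export
setMethod("orfRange", "AmpliconLayout", function(x) x@orf)

#' @describeIn AmpliconLayout-class Barcode intervals, upstream first.
#' @export
setGeneric("barcodeRegions", function(x) standardGeneric("barcodeRegions"))

#' @export
setMethod("barcodeRegions", "AmpliconLayout", function(x) x@barcodeRegions)

setMethod("show", "AmpliconLayout", function(object) {
    br <- object@barcodeRegions
    cat("AmpliconLayout '", object@name, "': ",
        length(object@refSeq), " bp reference\n", sep = "")
    cat("  ORF: ", IRanges::start(object@orf), "-", IRanges::end(object@orf),
        " (", IRanges::width(object@orf) / 3, " codons)\n", sep = "")
    lab <- if (length(br) == 2L) c("upstream", "downstream") else "barcode"
    for (i in seq_along(br))
        cat("  ", lab[i], " barcode: ", IRanges::start(br)[i], "-",
            IRanges::end(br)[i], "\n", sep = "")
})

#' Load an amplicon layout from a flat key-value config
#'
#' The config is plain text, one `key=value` per line: `reference` (path to a
#' FASTA file, or an inline sequence), `orf=start-end`, `barcode1=start-end`,
#' optionally `barcode2=start-end`, optionally `name`. Relative reference
#' paths are resolved against the config file's directory.
#'
#' @param config Path to a config file, or a character vector of config lines.
#' @return An [AmpliconLayout-class].
#' @export
loadLayout <- function(config) {
    lines <- if (length(config) == 1L && file.exists(config)) {
        readLines(config)
    } else as.character(config)
    dir <- if (length(config) == 1L && file.exists(config)) dirname(config) else "."
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
    keys <- vapply(kv, function(x) trimws(x[1]), "")
    vals <- vapply(kv, function(x) trimws(x[2]), "")
    getval <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    parseIv <- function(s) {
        p <- as.integer(strsplit(s, "-", fixed = TRUE)[[1]])
        if (length(p) != 2L || any(is.na(p)) || p[2] < p[1])
            stop("layout error: bad interval '", s, "'")
        p
    }
    refval <- getval("reference")
    if (is.na(refval)) stop("layout error: no reference given")
    refSeq <- if (grepl("^[ACGTNacgtn]+$", refval)) {
        toupper(refval)
    } else {
        path <- if (file.exists(refval)) refval else file.path(dir, refval)
        if (!file.exists(path)) stop("layout error: reference FASTA not found: ", refval)
        as.character(Biostrings::readDNAStringSet(path)[[1]])
    }
    if (is.na(getval("orf")) || is.na(getval("barcode1")))
        stop("layout error: orf and barcode1 are required")
    regions <- list(parseIv(getval("barcode1")))
    if (!is.na(getval("barcode2"))) regions <- c(regions, list(parseIv(getval("barcode2"))))
    nm <- getval("name"); if (is.na(nm)) nm <- "amplicon"
    ampliconLayout(refSeq, parseIv(getval("orf")), regions, name = nm)
}

#' Write an amplicon layout back to config + FASTA
#'
#' Inverse of [loadLayout()]: serializes the layout so that reloading yields
#' an identical object.
#'
#' @param layout An [AmpliconLayout-class].
#' @param dir Output directory (created if needed).
#' @return Path to the written config file, invisibly.
#' @export
writeLayout <- function(layout, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, paste0(layout@name, ".fa"))
    set <- Biostrings::DNAStringSet(layout@refSeq)
    names(set) <- layout@name
    Biostrings::writeXStringSet(set, fa)
    br <- layout@barcodeRegions
    lines <- c(paste0("name=", layout@name),
               paste0("reference=", basename(fa)),
               paste0("orf=", IRanges::start(layout@orf), "-", IRanges::end(layout@orf)),
               paste0("barcode1=", IRanges::start(br)[1], "-", IRanges::end(br)[1]))
    if (length(br) == 2L)
        lines <- c(lines, paste0("barcode2=", IRanges::start(br)[2], "-", IRanges::end(br)[2]))
    cfg <- file.path(dir, paste0(layout@name, ".layout"))
    writeLines(lines, cfg)
    invisible(cfg)
}

#' Maximal homopolymer runs in a sequence
#'
#' Long-read indel errors concentrate in homopolymer tracts; runs of length
#' >= 4 are the default annotation context for frameshift calls.
#'
#' @param seq DNA sequence (character or DNAString); ACGTN only.
#' @param minLen Minimum run length to report (>= 2).
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `base`, sorted by start; zero rows when there is no qualifying run.
#' @export
homopolymerRuns <- function(seq, minLen = 4L) {
    s <- as.character(seq)
    stopifnot(minLen >= 2L)
    if (grepl("[^ACGTN]", s)) stop("input error: non-ACGTN character")
    if (!nzchar(s))
        return(data.frame(start = integer(0), end = integer(0),
                          base = character(0), stringsAsFactors = FALSE))
    r <- rle(strsplit(s, "")[[1]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$lengths >= minLen
    data.frame(start = starts[keep], end = ends[keep], base = r$values[keep],
               stringsAsFactors = FALSE)
}
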