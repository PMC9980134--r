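#' @include AmpliconLayout-class.R
NULL

#' CloneCalls: final barcode-to-genotype map
#'
#' One row per called clone. Columns: `clusterId`, `barcode1` (upstream
#' consensus), optional `barcode2` (downstream), `virtualBarcode`, `nReads`,
#' `variants` (list column, the error-filtered nucleotide genotype),
#' `ntGenotype` (serialized form; "" = WT), `aaConsequences` (comma-joined
#' protein-change labels), `netFrame` (net reading-frame offset of the
#' genotype, 0/1/2), `homopolymerFs` (any frameshift indel at the 5' end of
#' a homopolymer run), and `flags` (comma-joined subset of
#' non_unique/remediable/chimera_suspect, filled by the QC step).
#'
#' @slot calls A [S4Vectors::DataFrame] as above.
#' @slot layout The [AmpliconLayout-class] used.
#' @export
setClass("CloneCalls",
    representation(calls = "DataFrame", layout = "AmpliconLayout"))

setValidity("CloneCalls", function(object) {
    need <- c("clusterId", "barcode1", "virtualBarcode", "nReads",
              "ntGenotype", "aaConsequences", "flags")
    miss <- setdiff(need, colnames(object@calls))
    if (length(miss)) return(paste("missing columns:", paste(miss, collapse = ", ")))
    TRUE
})

#' @describeIn CloneCalls-class The backing DataFrame.
#' @param x,object A CloneCalls.
#' @export
setGeneric("callsTable", function(x) standardGeneric("callsTable"))

#' @export
setMethod("callsTable", "CloneCalls", function(x) x@calls)

#' @describeIn CloneCalls-class Number of called clones.
#' @export
setMethod("length", "CloneCalls", function(x) nrow(x@calls))

setMethod("show", "CloneCalls", function(object) {
    d <- object@calls
    cat("CloneCalls: ", nrow(d), " clones\n", sep = "")
    if (nrow(d)) {
        cat("  WT: ", sum(d$ntGenotype == ""), "; median reads/clone: ",
            stats::median(d$nReads), "\n", sep = "")
        fl <- unlist(strsplit(d$flags[d$flags != ""], ","))
        if (length(fl)) {
            tb <- table(fl)
            cat("  flags:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
        }
    }
})

#' Write the barcode-genotype map
#'
#' @param x A [CloneCalls-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeCloneCalls <- function(x, path) {
    d <- x@calls
    out <- data.frame(cluster_id = d$clusterId,
                      virtual_barcode = d$virtualBarcode,
                      upstream_barcode = d$barcode1, stringsAsFactors = FALSE)
    if (!is.null(d$barcode2)) out$downstream_barcode <- d$barcode2
    out$n_reads <- d$nReads
    out$nt_genotype <- d$ntGenotype
    out$aa_consequences <- d$aaConsequences
    out$net_frame <- d$netFrame
    out$homopolymer_fs <- d$homopolymerFs
    out$flags <- d$flags
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
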