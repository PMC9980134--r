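#' @include ReadExtractions-class.R
NULL

#' CloneClusterSet: reads partitioned into presumptive clones
#'
#' Result of [clusterReads()]. Each cluster is a list with elements
#' `members` (row indices into the read table), `size`, `barcodes` (the
#' members' clustering barcodes), `filt` (error-filtered candidate-variant
#' table for the cluster), `isWT`, and `cons` (consensus clustering barcode).
#'
#' @slot clusters List of cluster records, ordered by decreasing size then
#'   consensus barcode.
#' @slot reads The [ReadExtractions-class] that was clustered.
#' @slot params Clustering parameters used (maxEd, jaccardMin, varQualMin,
#'   useVirtual).
#' @slot log data.frame audit of evaluated merges (ed level, pair, decision).
#' @export
setClass("CloneClusterSet",
    representation(clusters = "list", reads = "ReadExtractions",
                   params = "list", log = "data.frame"))

setValidity("CloneClusterSet", function(object) {
    mem <- unlist(lapply(object@clusters, `[[`, "members"))
    if (anyDuplicated(mem)) return("a read occurs in more than one cluster")
    if (any(vapply(object@clusters, `[[`, integer(1), "size") < 1L))
        return("empty cluster")
    TRUE
})

#' @describeIn CloneClusterSet-class List of cluster records.
#' @param x,object A CloneClusterSet.
#' @export
setGeneric("cloneClusters", function(x) standardGeneric("cloneClusters"))

#' @export
setMethod("cloneClusters", "CloneClusterSet", function(x) x@clusters)

#' @describeIn CloneClusterSet-class Number of clusters.
#' @export
setMethod("length", "CloneClusterSet", function(x) length(x@clusters))

#' @describeIn CloneClusterSet-class Cluster sizes (reads per clone).
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @export
setMethod("clusterSizes", "CloneClusterSet", function(x)
    vapply(x@clusters, `[[`, integer(1), "size"))

setMethod("show", "CloneClusterSet", function(object) {
    sz <- clusterSizes(object)
    cat("CloneClusterSet: ", length(sz), " clusters from ",
        sum(sz), " reads\n", sep = "")
    if (length(sz))
        cat("  sizes: median ", stats::median(sz), ", max ", max(sz),
            "; WT clusters: ",
            sum(vapply(object@clusters, `[[`, logical(1), "isWT")), "\n",
            sep = "")
})

#' Write the clusters table
#'
#' @param x A [CloneClusterSet-class].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
writeClusters <- function(x, path) {
    d <- readData(x@reads)
    rows <- lapply(seq_along(x@clusters), function(i) {
        cl <- x@clusters[[i]]
        data.frame(cluster_id = sprintf("clust%05d", i),
                   size = cl$size,
                   consensus_barcode = cl$cons,
                   members = paste(sort(d$readId[cl$members]), collapse = ","),
                   variants = formatVariants(cl$filt),
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) out <- data.frame(cluster_id = character(0),
        size = integer(0), consensus_barcode = character(0),
        members = character(0), variants = character(0))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
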