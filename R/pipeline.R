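## End-to-end pipeline: extract -> cluster -> consensus -> QC, with TSV
## reports. Outputs are deterministic: re-running on identical inputs and
## settings yields byte-identical files.

#' Run the clone-calling pipeline
#'
#' @param fastq Path to the input FASTQ.
#' @param layout An [AmpliconLayout-class] or path to a layout config for
#'   [loadLayout()].
#' @param outDir Output directory for the report TSVs (created if needed);
#'   NULL skips writing.
#' @param minBcQual Barcode-quality read filter threshold (default Q62).
#' @param maxEd Maximum barcode edit distance for cluster merging (default 2).
#' @param jaccardMin Jaccard threshold for genotype coherence (default 0.2).
#' @param varQualMin Error-filter quality threshold (default Q50).
#' @param homopolymerMin Homopolymer run length for frameshift annotation
#'   (default 4).
#' @param useVirtual Combine dual barcodes into a virtual barcode (default
#'   TRUE). When FALSE, clustering and uniqueness are keyed on the upstream
#'   barcode alone.
#' @param chimeras `"auto"` (detect when the layout has two barcodes),
#'   `"on"` (error on single-barcode layouts) or `"off"`.
#' @param bcQualStat `"min"` or `"mean"` barcode quality summary.
#' @param nWorkers Parallel workers for extraction (does not change results).
#' @return Invisibly, a list with `reads` ([ReadExtractions-class]),
#'   `clusters` ([CloneClusterSet-class]), `calls` ([CloneCalls-class]),
#'   `uniqueness`, `chimeras` (or NULL), `crossTab` (or NULL) and `summary`
#'   (named list of run statistics).
#' @export
runPipeline <- function(fastq, layout, outDir = NULL, minBcQual = 62L,
                        maxEd = 2L, jaccardMin = 0.2, varQualMin = 50L,
                        homopolymerMin = 4L, useVirtual = TRUE,
                        chimeras = c("auto", "on", "off"),
                        bcQualStat = c("min", "mean"), nWorkers = 1L) {
    chimeras <- match.arg(chimeras)
    bcQualStat <- match.arg(bcQualStat)
    if (is.character(layout)) layout <- loadLayout(layout)
    if (!file.exists(fastq)) stop("input FASTQ not found: ", fastq)
    dual <- length(barcodeRegions(layout)) == 2L
    if (chimeras == "on" && !dual)
        stop("chimera detection requested but the layout has a single barcode region")
    doChim <- dual && chimeras != "off"

    reads <- extractReads(fastq, layout, minBcQual = minBcQual,
                          bcQualStat = bcQualStat, nWorkers = nWorkers)
    cs <- clusterReads(reads, maxEd = maxEd, jaccardMin = jaccardMin,
                       varQualMin = varQualMin, useVirtual = useVirtual)
    calls <- callClones(cs, homopolymerMin = homopolymerMin)
    uniq <- classifyBarcodeUniqueness(calls,
        key = if (useVirtual || !dual) "virtual" else "upstream")
    chim <- if (doChim && length(calls) > 0L) detectChimeras(calls, maxEd = maxEd)
            else NULL
    calls <- flagCloneCalls(calls, uniq, chim)
    crossTab <- if (doChim && length(calls) > 0L && useVirtual) {
        ## faithful "virtual barcodes disabled" comparison: re-cluster the
        ## same extractions on the upstream barcode alone
        csUp <- clusterReads(reads, maxEd = maxEd, jaccardMin = jaccardMin,
                             varQualMin = varQualMin, useVirtual = FALSE)
        callsUp <- callClones(csUp, homopolymerMin = homopolymerMin)
        crossTabulateChimeraFlags(calls, callsUp, maxEd = maxEd)
    } else NULL

    d <- readData(reads)
    szHist <- table(clusterSizes(cs))
    nvar <- vapply(cloneClusters(cs), function(cl) nrow(cl$filt), integer(1))
    nGroups <- nrow(uniq)
    summary <- list(
        reads_in = nrow(d),
        reads_kept = sum(d$keep),
        dropped_unaligned = sum(d$dropReason == "unaligned"),
        dropped_no_barcode = sum(d$dropReason == "no_barcode"),
        dropped_low_bc_qual = sum(d$dropReason == "low_bc_qual"),
        n_clusters = length(cs),
        cluster_size_hist = paste(names(szHist), szHist, sep = ":", collapse = ","),
        variant_count_hist = paste(names(table(nvar)), table(nvar), sep = ":",
                                   collapse = ","),
        n_barcode_groups = nGroups,
        frac_non_unique = if (nGroups) mean(uniq$status != "unique") else NA,
        frac_remediable = if (nGroups)
            mean(uniq$status == "non_unique_remediable") else NA,
        n_chimera_sets = if (is.null(chim)) NA_integer_ else
            length(unique(chim$setId)))

    if (!is.null(outDir)) {
        if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
        writeExtractions(reads, file.path(outDir, "extractions.tsv"))
        writeClusters(cs, file.path(outDir, "clusters.tsv"))
        writeCloneCalls(calls, file.path(outDir, "clone_calls.tsv"))
        utils::write.table(uniq, file.path(outDir, "uniqueness.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (doChim)
            utils::write.table(
                if (is.null(chim)) data.frame(setId = integer(0)) else chim,
                file.path(outDir, "chimeras.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
        sm <- data.frame(key = names(summary),
                         value = vapply(summary, function(x)
                             as.character(x), ""), stringsAsFactors = FALSE)
        utils::write.table(sm, file.path(outDir, "summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(list(reads = reads, clusters = cs, calls = calls,
                   uniqueness = uniq, chimeras = chim, crossTab = crossTab,
                   summary = summary))
}

#' Score chimera detection against simulation ground truth
#'
#' @param result List returned by [runPipeline()] on a dual-barcode
#'   simulation with planted crossover templates.
#' @param readTruth,templates Truth tables from [simulateReads()].
#' @return List with `recall` (fraction of chimeric-template clusters
#'   appearing in a chimera set), `falseFlagRate` (fraction of clusters that
#'   are neither chimeric nor crossover donors yet appear in a set),
#'   `nChimericClusters`, and `clusterTruth` (per-cluster majority template
#'   with its flagged status, for downstream checks).
#' @export
evaluateChimeraDetection <- function(result, readTruth, templates) {
    cs <- result$clusters
    d <- readData(cs@reads)
    truthOf <- readTruth$templateId[match(d$readId, readTruth$readId)]
    clMajor <- vapply(seq_along(cloneClusters(cs)), function(i) {
        t <- truthOf[cloneClusters(cs)[[i]]$members]
        names(sort(table(t), decreasing = TRUE))[1]
    }, "")
    calls <- callsTable(result$calls)
    flagged <- calls$clusterId %in% result$chimeras$clusterId
    chimTab <- templates[!is.na(templates$donorA), , drop = FALSE]
    isChim <- clMajor %in% chimTab$cloneId
    donors <- unique(c(chimTab$donorA, chimTab$donorB))
    isDonor <- clMajor %in% donors
    list(recall = if (any(isChim)) mean(flagged[isChim]) else NA_real_,
         falseFlagRate = if (any(!isChim & !isDonor))
             mean(flagged[!isChim & !isDonor]) else NA_real_,
         nChimericClusters = sum(isChim),
         clusterTruth = data.frame(clusterId = calls$clusterId,
             template = clMajor, flagged = flagged,
             isChimera = isChim, isDonor = isDonor,
             stringsAsFactors = FALSE))
}

#' Score pipeline output against simulation ground truth
#'
#' @param result List returned by [runPipeline()].
#' @param readTruth `readTruth` table from [simulateReads()].
#' @param templates `templates` table from [simulateReads()].
#' @return List with `ari` (adjusted Rand index between called clusters and
#'   true templates over kept reads), `genotypeExact` (fraction of
#'   non-chimeric clones whose called genotype matches truth exactly, via
#'   majority cluster-template mapping), `clonesDetected` (fraction of
#'   clones receiving any cluster), and `nKept`.
#' @export
evaluateRecovery <- function(result, readTruth, templates) {
    cs <- result$clusters
    d <- readData(cs@reads)
    member <- integer(nrow(d))
    for (i in seq_along(cloneClusters(cs)))
        member[cloneClusters(cs)[[i]]$members] <- i
    kept <- which(member > 0L)
    truthOf <- readTruth$templateId[match(d$readId, readTruth$readId)]
    ari <- adjustedRandIndex(member[kept], truthOf[kept])

    ## majority template per cluster
    calls <- callsTable(result$calls)
    clMajor <- vapply(seq_along(cloneClusters(cs)), function(i) {
        t <- truthOf[cloneClusters(cs)[[i]]$members]
        names(sort(table(t), decreasing = TRUE))[1]
    }, "")
    clones <- templates[is.na(templates$donorA), , drop = FALSE]
    exact <- logical(nrow(clones))
    for (i in seq_len(nrow(clones))) {
        cid <- clones$cloneId[i]
        cl <- which(clMajor == cid)
        if (!length(cl)) next
        big <- cl[which.max(calls$nReads[cl])]
        trueKeys <- variantKey(parseVariants(clones$genotype[i]))
        callKeys <- variantKey(result$calls@calls$variants[[big]])
        exact[i] <- setequal(trueKeys, callKeys)
    }
    list(ari = ari, genotypeExact = mean(exact),
         clonesDetected = mean(clones$cloneId %in% clMajor),
         nKept = length(kept))
}
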