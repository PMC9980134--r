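## Seeded simulator for barcoded clone libraries and HiFi-like reads with
## ground truth. Emulates: clones carrying 0-n variants, lognormal read
## depth per clone, substitution/indel sequencing errors with elevated indel
## rates inside homopolymer runs, per-read barcode errors, planted
## non-unique barcodes, and PCR-crossover chimeric templates.

#' Simulation parameters
#'
#' Defaults describe a HiFi-like library: per-base substitution rate 1e-3
#' and indel rate 5e-4 (split between insertions and deletions), indel rates
#' multiplied inside homopolymer runs of length >= 4, a Poisson(3) mutation
#' load per clone, ~10 reads per clone (lognormal), a 2% per-read chance of
#' a barcode error, and 5% planted non-unique barcodes. Erroneous basecalls
#' receive low quality scores (median ~Q25); correct basecalls high ones
#' (median ~Q90); barcode errors draw from a 70/30 low/high quality mixture
#' so that a minority of barcode errors survives the Q62 read filter, as
#' systematic miscalls do.
#'
#' @param nClones Number of clones.
#' @param barcodeLen Barcode length used by [exampleLayout()].
#' @param variantsPerClone Poisson mean of true variants per clone.
#' @param readsPerClone `c(meanlog, sdlog)` of the lognormal read count.
#' @param subRate,insRate,delRate Per-base error rates in [0,1].
#' @param homopolymerIndelMultiplier Indel-rate multiplier inside
#'   homopolymer runs of length >= 4 (>= 1).
#' @param barcodeErrorRate Per-read probability of one barcode error
#'   (substitution 80% / insertion 10% / deletion 10%).
#' @param fracNonuniqueBarcodes Fraction of clones re-using another clone's
#'   barcode(s).
#' @param fracChimericTemplates Chimeric (crossover) templates, as a
#'   fraction of `nClones`.
#' @param variantTypeProbs Probabilities for SNV/insertion/deletion truth
#'   variants.
#' @return Named list of validated parameters.
#' @export
simParams <- function(nClones = 100L, barcodeLen = 25L, variantsPerClone = 3,
                      readsPerClone = c(meanlog = log(10), sdlog = 0.25),
                      subRate = 0.001, insRate = 0.00025, delRate = 0.00025,
                      homopolymerIndelMultiplier = 5,
                      barcodeErrorRate = 0.02, fracNonuniqueBarcodes = 0.05,
                      fracChimericTemplates = 0,
                      variantTypeProbs = c(SNV = 0.7, ins = 0.15, del = 0.15)) {
    p <- list(nClones = as.integer(nClones), barcodeLen = as.integer(barcodeLen),
              variantsPerClone = variantsPerClone,
              readsPerClone = readsPerClone, subRate = subRate,
              insRate = insRate, delRate = delRate,
              homopolymerIndelMultiplier = homopolymerIndelMultiplier,
              barcodeErrorRate = barcodeErrorRate,
              fracNonuniqueBarcodes = fracNonuniqueBarcodes,
              fracChimericTemplates = fracChimericTemplates,
              variantTypeProbs = variantTypeProbs)
    rates <- c(p$subRate, p$insRate, p$delRate, p$barcodeErrorRate,
               p$fracNonuniqueBarcodes, p$fracChimericTemplates)
    stopifnot(all(rates >= 0 & rates <= 1),
              p$homopolymerIndelMultiplier >= 1)
    p
}

#' Deterministic example amplicon layout
#'
#' A fixed synthetic dual-barcode amplicon: 30 bp flank, upstream barcode
#' (N run), 20 bp spacer, a 450 bp ORF (ATG + 148 sense codons + TAA),
#' 20 bp spacer, downstream barcode, 30 bp flank. The sequence is built
#' under an internal fixed seed and does not depend on the caller's RNG.
#'
#' @param barcodeLen Barcode region length (default 25).
#' @param nCodons Sense codons between start and stop (default 148).
#' @param dual Include the downstream barcode region (default TRUE).
#' @return An [AmpliconLayout-class].
#' @export
exampleLayout <- function(barcodeLen = 25L, nCodons = 148L, dual = TRUE) {
    withSeed(20210907L, {
        bases <- c("A", "C", "G", "T")
        rand <- function(n) paste(sample(bases, n, TRUE), collapse = "")
        sense <- setdiff(names(Biostrings::GENETIC_CODE),
                         names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == "*"])
        orf <- paste0("ATG", paste(sample(sense, nCodons, TRUE), collapse = ""), "TAA")
        parts <- c(rand(30L), strrep("N", barcodeLen), rand(20L), orf, rand(20L))
        bc1 <- c(31L, 30L + barcodeLen)
        orfStart <- 30L + barcodeLen + 21L
        orfEnd <- orfStart + nchar(orf) - 1L
        regions <- list(bc1)
        if (dual) {
            bc2 <- c(orfEnd + 21L, orfEnd + 20L + barcodeLen)
            parts <- c(parts, strrep("N", barcodeLen), rand(30L))
            regions <- c(regions, list(bc2))
        } else {
            parts <- c(parts, rand(30L))
        }
        ampliconLayout(paste(parts, collapse = ""), c(orfStart, orfEnd),
                       regions, name = "simAmplicon")
    })
}

.randBarcode <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE),
                                    collapse = "")

## Draw one clone's true variant set over the ORF (left-aligned).
.drawVariants <- function(layout, params) {
    refseq <- as.character(referenceSeq(layout))
    os <- IRanges::start(orfRange(layout)); oe <- IRanges::end(orfRange(layout))
    k <- stats::rpois(1L, params$variantsPerClone)
    if (k == 0L) return(emptyVariants())
    bases <- c("A", "C", "G", "T")
    for (try in 1:50) {
        pos <- sort(sample(os:(oe - 4L), k))
        if (k == 1L || min(diff(pos)) >= 5L) break
    }
    type <- sample(c("SNV", "ins", "del"), k, TRUE, prob = params$variantTypeProbs)
    ref <- alt <- character(k)
    for (i in seq_len(k)) {
        b <- substr(refseq, pos[i], pos[i])
        if (type[i] == "SNV") {
            ref[i] <- b
            alt[i] <- sample(setdiff(bases, b), 1L)
        } else if (type[i] == "ins") {
            len <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
            ref[i] <- ""
            alt[i] <- paste(sample(bases, len, TRUE), collapse = "")
        } else {
            len <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
            ref[i] <- substr(refseq, pos[i], pos[i] + len - 1L)
            alt[i] <- ""
        }
    }
    v <- variantTable(pos, ref, alt, rep(93L, k))
    leftAlignVariants(v, refseq)
}

#' Simulate a clone library
#'
#' Draws random barcodes (uniform ACGT per position), plants a fraction of
#' non-unique barcodes (a later clone re-uses an earlier clone's barcodes
#' while carrying a different genotype), and draws each clone's variants
#' uniformly over the ORF with a 70/15/15 SNV/insertion/deletion mix.
#'
#' @param layout An [AmpliconLayout-class].
#' @param params From [simParams()].
#' @param seed Integer seed; fixes the clone table completely.
#' @return data.frame with `cloneId`, `barcode1`, (`barcode2`),
#'   `virtualBarcode`, `variants` (list column, left-aligned), `genotype`
#'   (serialized), `seq` (the clone's template sequence).
#' @export
simulateClones <- function(layout, params = simParams(), seed = 1L) {
    withSeed(seed, {
        n <- params$nClones
        br <- barcodeRegions(layout)
        dual <- length(br) == 2L
        refseq <- as.character(referenceSeq(layout))
        widths <- IRanges::width(br)
        bc1 <- vapply(seq_len(n), function(i) .randBarcode(widths[1]), "")
        bc2 <- if (dual) vapply(seq_len(n), function(i) .randBarcode(widths[2]), "")
               else rep(NA_character_, n)
        variants <- lapply(seq_len(n), function(i) .drawVariants(layout, params))
        ## plant non-unique barcodes
        nNon <- round(params$fracNonuniqueBarcodes * n)
        if (nNon > 0L && n >= 2L) {
            recipients <- sample(2:n, nNon)
            for (r in recipients) {
                donor <- sample(setdiff(seq_len(n), recipients), 1L)
                bc1[r] <- bc1[donor]
                if (dual) bc2[r] <- bc2[donor]
                while (setequal(variantKey(variants[[r]]),
                                variantKey(variants[[donor]]))) {
                    variants[[r]] <- .drawVariants(layout, params)
                }
            }
        }
        fill <- function(i) {
            s <- refseq
            substr(s, IRanges::start(br)[1], IRanges::end(br)[1]) <- bc1[i]
            if (dual)
                substr(s, IRanges::start(br)[2], IRanges::end(br)[2]) <- bc2[i]
            applyVariants(s, variants[[i]])
        }
        seqs <- vapply(seq_len(n), fill, "")
        out <- data.frame(cloneId = sprintf("clone%04d", seq_len(n)),
                          barcode1 = bc1, stringsAsFactors = FALSE)
        if (dual) out$barcode2 <- bc2
        out$virtualBarcode <- if (dual) paste0(bc1, bc2) else bc1
        out$variants <- I(variants)
        out$genotype <- vapply(variants, formatVariants, "")
        out$seq <- seqs
        out
    })
}

## Build chimeric templates: upstream portion (incl. upstream barcode) from
## clone A, downstream portion (incl. downstream barcode) from clone B,
## crossover point uniform within the ORF (kept clear of donor variants so
## the crossover genotype is exactly the positional union).
.makeChimeras <- function(clones, layout, params) {
    nChim <- round(params$fracChimericTemplates * params$nClones)
    if (nChim == 0L) return(NULL)
    if (is.null(clones$barcode2))
        stop("chimeric templates require a dual-barcode layout")
    refseq <- as.character(referenceSeq(layout))
    br <- barcodeRegions(layout)
    os <- IRanges::start(orfRange(layout)); oe <- IRanges::end(orfRange(layout))
    rows <- list()
    for (i in seq_len(nChim)) {
        ab <- sample(nrow(clones), 2L)
        va <- clones$variants[[ab[1]]]; vb <- clones$variants[[ab[2]]]
        avoid <- c(va$pos, vb$pos)
        x <- os
        for (try in 1:100) {
            x <- sample((os + 1L):(oe - 1L), 1L)
            if (!length(avoid) || min(abs(avoid - x)) > 6L) break
        }
        v <- rbind(va[va$pos <= x, , drop = FALSE], vb[vb$pos > x, , drop = FALSE])
        v <- v[order(v$pos, v$ref, v$alt), , drop = FALSE]
        s <- refseq
        substr(s, IRanges::start(br)[1], IRanges::end(br)[1]) <-
            clones$barcode1[ab[1]]
        substr(s, IRanges::start(br)[2], IRanges::end(br)[2]) <-
            clones$barcode2[ab[2]]
        rows[[i]] <- data.frame(cloneId = sprintf("chimera%04d", i),
            barcode1 = clones$barcode1[ab[1]],
            barcode2 = clones$barcode2[ab[2]],
            virtualBarcode = paste0(clones$barcode1[ab[1]], clones$barcode2[ab[2]]),
            genotype = formatVariants(v), seq = applyVariants(s, v),
            donorA = clones$cloneId[ab[1]], donorB = clones$cloneId[ab[2]],
            crossover = x, stringsAsFactors = FALSE)
        rows[[i]]$variants <- I(list(v))
    }
    do.call(rbind, rows)
}

.qualCorrect <- function(n) pmin(93L, pmax(1L, as.integer(round(stats::rnorm(n, 90, 3)))))
.qualError <- function(n) pmin(93L, pmax(3L, as.integer(round(stats::rnorm(n, 25, 8)))))
.qualBarcodeError <- function(n) {
    hi <- stats::runif(n) < 0.3
    q <- integer(n)
    q[hi] <- pmin(93L, pmax(3L, as.integer(round(stats::rnorm(sum(hi), 75, 5)))))
    q[!hi] <- .qualError(sum(!hi))
    q
}

## One read from a template: vectorized error planting outside the barcode
## regions, then an optional single barcode error, then random orientation.
.simulateOneRead <- function(tmplChars, inBc, indelMult, params) {
    L <- length(tmplChars)
    bases <- c("A", "C", "G", "T")
    sub <- !inBc & stats::runif(L) < params$subRate
    del <- !inBc & stats::runif(L) < params$delRate * indelMult
    ins <- !inBc & stats::runif(L) < params$insRate * indelMult
    chars <- tmplChars
    if (any(sub)) {
        chars[sub] <- vapply(which(sub), function(i)
            sample(setdiff(bases, tmplChars[i]), 1L), "")
    }
    qual <- .qualCorrect(L)
    qual[sub] <- .qualError(sum(sub))
    ## flanks of deletions lose confidence
    for (i in which(del)) {
        j <- i + 1L
        while (j <= L && del[j]) j <- j + 1L
        if (j <= L) qual[j] <- .qualError(1L)
    }
    keep <- !del
    mainKey <- which(keep) * 2L
    outChars <- chars[keep]; outQual <- qual[keep]; outSrc <- which(keep)
    if (any(ins)) {
        ii <- which(ins)
        insChars <- sample(bases, length(ii), TRUE)
        outChars <- c(outChars, insChars)
        outQual <- c(outQual, .qualError(length(ii)))
        outSrc <- c(outSrc, rep(NA_integer_, length(ii)))
        ord <- order(c(mainKey, ii * 2L + 1L))
        outChars <- outChars[ord]; outQual <- outQual[ord]; outSrc <- outSrc[ord]
    }
    ## per-read barcode error
    if (stats::runif(1) < params$barcodeErrorRate) {
        bcReadIdx <- which(!is.na(outSrc) & inBc[outSrc])
        if (length(bcReadIdx)) {
            at <- sample(bcReadIdx, 1L)
            kind <- sample(c("sub", "ins", "del"), 1L, prob = c(0.8, 0.1, 0.1))
            if (kind == "sub") {
                outChars[at] <- sample(setdiff(bases, outChars[at]), 1L)
                outQual[at] <- .qualBarcodeError(1L)
            } else if (kind == "ins") {
                outChars <- append(outChars, sample(bases, 1L), after = at)
                outQual <- append(outQual, .qualBarcodeError(1L), after = at)
            } else {
                outChars <- outChars[-at]
                outQual <- outQual[-at]
            }
        }
    }
    if (stats::runif(1) < 0.5) {
        comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
        outChars <- rev(unname(comp[outChars]))
        outQual <- rev(outQual)
    }
    list(seq = paste(outChars, collapse = ""), qual = outQual)
}

#' Simulate HiFi-like reads from a clone table
#'
#' Draws a lognormal read count per template, plants substitution and indel
#' errors at the configured per-base rates (indel rates multiplied inside
#' homopolymer runs of length >= 4 of the template), assigns qualities
#' anti-correlated with the planted errors, optionally injects one barcode
#' error per read with probability `barcodeErrorRate`, randomizes read
#' orientation, and (for dual-barcode layouts) emits chimeric crossover
#' templates at the configured fraction.
#'
#' @param clones Output of [simulateClones()].
#' @param layout An [AmpliconLayout-class].
#' @param params From [simParams()].
#' @param seed Integer seed; the emitted reads are byte-reproducible.
#' @return List with `reads` (data.frame: readId, seq, qual string),
#'   `readTruth` (readId, templateId, isChimera), and `templates` (the clone
#'   table extended with any chimeric templates, including donor ids and
#'   crossover points).
#' @export
simulateReads <- function(clones, layout, params = simParams(), seed = 1L) {
    withSeed(seed, {
        chim <- .makeChimeras(clones, layout, params)
        clones2 <- clones
        clones2$donorA <- clones2$donorB <- NA_character_
        clones2$crossover <- NA_integer_
        templates <- rbind(clones2[, c("cloneId", "barcode1",
            if (!is.null(clones$barcode2)) "barcode2", "virtualBarcode",
            "variants", "genotype", "seq", "donorA", "donorB", "crossover")],
            if (!is.null(chim)) chim[, c("cloneId", "barcode1", "barcode2",
                "virtualBarcode", "variants", "genotype", "seq", "donorA",
                "donorB", "crossover")])
        br <- barcodeRegions(layout)
        readRows <- vector("list", nrow(templates))
        truthRows <- vector("list", nrow(templates))
        counter <- 0L
        for (t in seq_len(nrow(templates))) {
            tmpl <- templates$seq[t]
            tmplChars <- strsplit(tmpl, "")[[1]]
            L <- length(tmplChars)
            ## barcode coordinates on this template: upstream region is
            ## unshifted; downstream shifts by the net ORF indel delta
            delta <- L - length(referenceSeq(layout))
            inBc <- rep(FALSE, L)
            inBc[IRanges::start(br)[1]:IRanges::end(br)[1]] <- TRUE
            if (length(br) == 2L)
                inBc[(IRanges::start(br)[2] + delta):(IRanges::end(br)[2] + delta)] <- TRUE
            runs <- homopolymerRuns(tmpl, 4L)
            indelMult <- rep(1, L)
            for (r in seq_len(nrow(runs)))
                indelMult[runs$start[r]:runs$end[r]] <- params$homopolymerIndelMultiplier
            nReads <- max(1L, as.integer(round(stats::rlnorm(1,
                params$readsPerClone[[1]], params$readsPerClone[[2]]))))
            ids <- character(nReads); seqs <- character(nReads); quals <- character(nReads)
            for (k in seq_len(nReads)) {
                counter <- counter + 1L
                rd <- .simulateOneRead(tmplChars, inBc, indelMult, params)
                ids[k] <- sprintf("read%06d", counter)
                seqs[k] <- rd$seq
                quals[k] <- intToPhred(rd$qual)
            }
            readRows[[t]] <- data.frame(readId = ids, seq = seqs, qual = quals,
                                        stringsAsFactors = FALSE)
            truthRows[[t]] <- data.frame(readId = ids,
                templateId = templates$cloneId[t],
                isChimera = !is.na(templates$donorA[t]),
                stringsAsFactors = FALSE)
        }
        list(reads = do.call(rbind, readRows),
             readTruth = do.call(rbind, truthRows),
             templates = templates)
    })
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame from [simulateReads()] (`$reads`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
writeSimFastq <- function(reads, path) {
    lines <- character(4L * nrow(reads))
    if (nrow(reads)) {
        lines[seq(1, length(lines), 4)] <- paste0("@", reads$readId)
        lines[seq(2, length(lines), 4)] <- reads$seq
        lines[seq(3, length(lines), 4)] <- "+"
        lines[seq(4, length(lines), 4)] <- reads$qual
    }
    writeLines(lines, path)
    invisible(path)
}

#' Simulate a complete library fixture
#'
#' Convenience wrapper: clone table, reads and truth tables under one seed,
#' optionally written to a directory (FASTQ + layout config + truth TSVs).
#'
#' @param params From [simParams()].
#' @param layout An [AmpliconLayout-class] (default [exampleLayout()]).
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return List with `layout`, `clones`, `reads`, `readTruth`, `templates`,
#'   and (when `dir` is given) the written file paths.
#' @export
simulateLibrary <- function(params = simParams(), layout = exampleLayout(),
                            seed = 1L, dir = NULL) {
    clones <- simulateClones(layout, params, seed)
    sim <- simulateReads(clones, layout, params, seed + 1L)
    out <- list(layout = layout, clones = clones, reads = sim$reads,
                readTruth = sim$readTruth, templates = sim$templates)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        out$fastq <- writeSimFastq(sim$reads, file.path(dir, "reads.fastq"))
        out$layoutConfig <- writeLayout(layout, dir)
        tmpl <- sim$templates
        tmpl$variants <- NULL
        utils::write.table(tmpl, file.path(dir, "clone_truth.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(sim$readTruth, file.path(dir, "read_truth.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    out
}
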