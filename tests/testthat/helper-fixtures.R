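## Shared fixture builders: all data is constructed in code at test time.

BASES <- c("A", "C", "G", "T")

randSeq <- function(n) paste(sample(BASES, n, TRUE), collapse = "")

## A small dual-barcode layout built explicitly (not random): 6 bp flank,
## 6 bp upstream barcode, 4 bp spacer, 30 bp ORF, 4 bp spacer, 6 bp
## downstream barcode, 6 bp flank. The ORF contains an AAAA run.
tinyLayout <- function(dual = TRUE) {
    orf <- "ATGCATAAAACTGTTTCCAGGCGACGGTAA"   # 10 codons
    stopifnot(nchar(orf) == 30)
    ref <- paste0("GATTAC", strrep("N", 6), "CCGT", orf, "TTAC",
                  if (dual) strrep("N", 6) else "", "AGGCTA")
    regions <- list(c(7, 12))
    if (dual) regions <- c(regions, list(c(51, 56)))
    ampliconLayout(ref, c(17, 46), regions, name = "tiny")
}

## One random edit applied to a barcode string.
mutateBarcode <- function(s) {
    n <- nchar(s)
    i <- sample(n, 1)
    op <- sample(c("sub", "ins", "del"), 1)
    if (op == "sub") {
        b <- substr(s, i, i)
        paste0(substr(s, 1, i - 1), sample(setdiff(BASES, b), 1),
               substr(s, i + 1, n))
    } else if (op == "ins") {
        paste0(substr(s, 1, i), sample(BASES, 1), substr(s, i + 1, n))
    } else {
        paste0(substr(s, 1, i - 1), substr(s, i + 1, n))
    }
}

randVariants <- function(k, qmin = 60, qmax = 93) {
    if (k == 0) return(emptyVariants())
    pos <- sample(40:140, k)
    ref <- sample(BASES, k, TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
    variantTable(pos, ref, alt, sample(qmin:qmax, k, TRUE))
}

## A random micro-library at the read-record level (no FASTQ, no alignment):
## a few clones with 9 bp barcodes, some sharing a barcode (non-unique),
## some reads carrying barcode errors (satellites) and/or a private noise
## variant of variable quality. At most `maxReads` reads.
makeMicroLibrary <- function(seed, maxReads = 50) {
    set.seed(seed)
    nBc <- sample(2:4, 1)
    baseBc <- unique(replicate(nBc, randSeq(9)))
    readId <- barcode <- character(0)
    varList <- list()
    cloneOf <- integer(0)
    counter <- 0
    cloneId <- 0
    for (b in baseBc) {
        for (cl in seq_len(sample(1:2, 1))) {
            cloneId <- cloneId + 1
            genotype <- randVariants(sample(0:3, 1))
            nReads <- sample(1:10, 1)
            for (r in seq_len(nReads)) {
                counter <- counter + 1
                bc <- b
                if (runif(1) < 0.2) bc <- mutateBarcode(bc)
                if (runif(1) < 0.05) bc <- mutateBarcode(bc)
                v <- genotype
                if (nrow(v)) v$qual <- sample(60:93, nrow(v), TRUE)
                if (runif(1) < 0.3) {
                    noise <- randVariants(1, qmin = 5, qmax = 60)
                    v <- rbind(v, noise)
                    v <- v[!duplicated(paste0(v$pos, v$ref, v$alt)), ]
                }
                readId <- c(readId, sprintf("r%03d", counter))
                barcode <- c(barcode, bc)
                varList <- c(varList, list(v))
                cloneOf <- c(cloneOf, cloneId)
            }
        }
    }
    keep <- seq_len(min(length(readId), maxReads))
    list(readId = readId[keep], barcode = barcode[keep],
         varList = varList[keep], cloneOf = cloneOf[keep])
}

## Build a CloneCalls object directly from plain fields (for QC tests).
makeCalls <- function(barcode1, barcode2 = NULL, nReads, genotypes,
                      layout = tinyLayout(dual = !is.null(barcode2))) {
    n <- length(barcode1)
    variants <- lapply(genotypes, parseVariants)
    virt <- if (is.null(barcode2)) barcode1 else paste0(barcode1, barcode2)
    calls <- S4Vectors::DataFrame(
        clusterId = sprintf("clust%05d", seq_len(n)),
        barcode1 = barcode1, virtualBarcode = virt,
        nReads = as.integer(nReads),
        ntGenotype = vapply(variants, formatVariants, ""),
        aaConsequences = rep("", n), netFrame = rep(0L, n),
        homopolymerFs = rep(FALSE, n), flags = rep("", n))
    calls$variants <- variants
    if (!is.null(barcode2)) calls$barcode2 <- barcode2
    methods::new("CloneCalls", calls = calls, layout = layout)
}

## Build a synthetic perfect read (sequence + qualities) for a layout, with
## given barcodes and variants applied; returns seq and integer quals.
perfectRead <- function(layout, bc1, bc2 = NULL, variants = emptyVariants(),
                        qual = 93L) {
    ref <- as.character(referenceSeq(layout))
    br <- barcodeRegions(layout)
    substr(ref, IRanges::start(br)[1], IRanges::end(br)[1]) <- bc1
    if (!is.null(bc2))
        substr(ref, IRanges::start(br)[2], IRanges::end(br)[2]) <- bc2
    s <- applyVariants(ref, variants)
    list(seq = s, qual = rep(as.integer(qual), nchar(s)))
}
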