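lay <- tinyLayout()

test_that("alignment scores match an independent Gotoh oracle", {
    bc1 <- "ACGTCA"; bc2 <- "TTGACA"
    rd <- perfectRead(lay, bc1, bc2)
    ref <- as.character(referenceSeq(lay))

    a <- alignRead(rd$seq, rd$qual, lay)
    expect_equal(a$score, oracleGotohScore(rd$seq, ref))
    expect_equal(a$score, nchar(rd$seq))      # identity: all matches
    cols <- BarcodeClones:::alignmentColumns(a)
    expect_true(all(cols$type == "M"))

    ## one substitution: exactly one mismatch column
    sub <- rd$seq
    substr(sub, 20, 20) <- if (substr(sub, 20, 20) == "A") "C" else "A"
    a2 <- alignRead(sub, rd$qual, lay)
    expect_equal(a2$score, oracleGotohScore(sub, ref))
    expect_equal(sum(BarcodeClones:::alignmentColumns(a2)$type == "X"), 1L)

    ## 2 bp deletion: affine gaps force one contiguous gap of length 2
    del <- paste0(substr(rd$seq, 1, 29), substr(rd$seq, 32, nchar(rd$seq)))
    a3 <- alignRead(del, rep(93L, nchar(del)), lay)
    expect_equal(a3$score, oracleGotohScore(del, ref))
    dcols <- BarcodeClones:::alignmentColumns(a3)
    expect_equal(sum(dcols$type == "D"), 2L)
    expect_equal(diff(which(dcols$type == "D")), 1L)

    ## property: random mutated reads still match the oracle score
    set.seed(99)
    for (rep in 1:15) {
        s <- rd$seq
        for (k in 1:2) {
            i <- sample(15:40, 1)
            substr(s, i, i) <- sample(c("A", "C", "G", "T"), 1)
        }
        if (runif(1) < 0.5) s <- paste0(substr(s, 1, 25), substr(s, 27, nchar(s)))
        a4 <- alignRead(s, rep(93L, nchar(s)), lay)
        expect_equal(a4$score, oracleGotohScore(s, ref))
    }
})

test_that("reverse-strand reads are recognized and re-oriented", {
    rd <- perfectRead(lay, "ACGTCA", "TTGACA")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rd$seq)))
    a <- alignRead(rc, rd$qual, lay)
    expect_equal(a$orientation, "-")
    expect_equal(a$read, rd$seq)
    expect_equal(nrow(extractVariants(a, lay)), 0L)
    bx <- extractBarcodes(a, lay)
    expect_equal(bx$barcodes, c("ACGTCA", "TTGACA"))
})

test_that("barcode extraction handles indels inside the region", {
    bc1 <- "ACGTCA"; bc2 <- "TTGACA"
    rd <- perfectRead(lay, bc1, bc2)

    a <- alignRead(rd$seq, rd$qual, lay)
    bx <- extractBarcodes(a, lay)
    expect_true(bx$ok)
    expect_equal(bx$barcodes, c(bc1, bc2))
    expect_equal(bx$bcQual, 93L)

    ## 1 nt deletion inside the upstream region -> 5 nt barcode
    del <- paste0(substr(rd$seq, 1, 8), substr(rd$seq, 10, nchar(rd$seq)))
    bxd <- extractBarcodes(alignRead(del, rep(93L, nchar(del)), lay), lay)
    expect_equal(nchar(bxd$barcodes[1]), 5L)
    expect_equal(bxd$barcodes[2], bc2)

    ## insertion strictly inside the region -> 7 nt barcode
    ins <- paste0(substr(rd$seq, 1, 9), "A", substr(rd$seq, 10, nchar(rd$seq)))
    bxi <- extractBarcodes(alignRead(ins, rep(93L, nchar(ins)), lay), lay)
    expect_equal(nchar(bxi$barcodes[1]), 7L)
    ## and the inserted event does not become a candidate variant
    expect_equal(nrow(extractVariants(alignRead(ins, rep(93L, nchar(ins)), lay),
                                      lay)), 0L)
})

test_that("barcode-quality filter has the documented boundary", {
    expect_true(filterBarcodeQuality(93L, 62L))
    expect_false(filterBarcodeQuality(61L, 62L))   # strictly below drops
    expect_true(filterBarcodeQuality(62L, 62L))    # at threshold keeps
    ## monotone in the threshold: raising it never keeps a dropped read
    set.seed(5)
    for (rep in 1:30) {
        q <- sample(0:93, 1)
        t1 <- sample(0:93, 1); t2 <- min(93L, t1 + sample(1:20, 1))
        if (!filterBarcodeQuality(q, t1)) expect_false(filterBarcodeQuality(q, t2))
    }
})

test_that("candidate variants are extracted with positions and qualities", {
    rd <- perfectRead(lay, "ACGTCA", "TTGACA")
    a <- alignRead(rd$seq, rd$qual, lay)
    expect_equal(nrow(extractVariants(a, lay)), 0L)

    ## one substitution at a known ORF position with a known quality
    s <- rd$seq; q <- rd$qual
    ref <- as.character(referenceSeq(lay))
    p <- 20L                                   # inside the ORF (17..46)
    old <- substr(ref, p, p)
    substr(s, p, p) <- if (old == "C") "T" else "C"
    q[p] <- 77L
    v <- extractVariants(alignRead(s, q, lay), lay)
    expect_equal(nrow(v), 1L)
    expect_equal(v$pos, p)
    expect_equal(v$ref, old)
    expect_equal(v$vtype, "SNV")
    expect_equal(v$qual, 77L)

    ## adjacent substitutions merge into one MNV
    s2 <- rd$seq
    substr(s2, 36, 37) <- if (substr(ref, 36, 36) == "A") "CC" else "AA"
    v2 <- extractVariants(alignRead(s2, rd$qual, lay), lay)
    expect_equal(nrow(v2), 1L)
    expect_equal(v2$vtype, "MNV")
    expect_equal(nchar(v2$ref), 2L)
})

test_that("indels are left-aligned against homopolymer runs", {
    ## tinyLayout ORF has an AAAA run at reference 23..26
    runs <- homopolymerRuns(referenceSeq(lay), 4)
    expect_true(any(runs$start == 23L & runs$base == "A"))
    rd <- perfectRead(lay, "ACGTCA", "TTGACA")
    ## delete the *last* A of the run: report must be at the run start
    del <- paste0(substr(rd$seq, 1, 25), substr(rd$seq, 27, nchar(rd$seq)))
    v <- extractVariants(alignRead(del, rep(93L, nchar(del)), lay), lay)
    expect_equal(nrow(v), 1L)
    expect_equal(v$vtype, "deletion")
    expect_equal(v$pos, 23L)
    expect_equal(v$ref, "A")
    ## exhaustive-shift oracle: deleting any A of the run is equivalent
    for (i in 23:26) {
        di <- paste0(substr(rd$seq, 1, i - 1), substr(rd$seq, i + 1, nchar(rd$seq)))
        vi <- extractVariants(alignRead(di, rep(93L, nchar(di)), lay), lay)
        expect_equal(variantKey(vi), "23:A>")
    }
})

test_that("extraction recovers planted variants exactly on clean reads", {
    set.seed(31)
    ref <- as.character(referenceSeq(lay))
    for (rep in 1:20) {
        k <- sample(0:2, 1)
        truth <- if (k == 0) emptyVariants() else {
            pos <- sort(sample(seq(18, 42, by = 8), k))
            type <- sample(c("SNV", "ins", "del"), k, TRUE)
            refA <- altA <- character(k)
            for (i in seq_len(k)) {
                b <- substr(ref, pos[i], pos[i])
                if (type[i] == "SNV") {
                    refA[i] <- b; altA[i] <- sample(setdiff(BASES, b), 1)
                } else if (type[i] == "ins") {
                    refA[i] <- ""; altA[i] <- sample(BASES, 1)
                } else {
                    refA[i] <- b; altA[i] <- ""
                }
            }
            leftAlignVariants(variantTable(pos, refA, altA, rep(93L, k)), ref)
        }
        rd <- perfectRead(lay, randSeq(6), randSeq(6), truth)
        v <- extractVariants(alignRead(rd$seq, rd$qual, lay), lay)
        expect_setequal(variantKey(v), variantKey(truth))
    }
})

test_that("extractReads processes FASTQ end to end and drops by reason", {
    dir <- withr::local_tempdir()
    rd1 <- perfectRead(lay, "ACGTCA", "TTGACA")              # clean
    rd2 <- perfectRead(lay, "AAATCA", "TTGACA")              # low bc qual
    rd2$qual[8] <- 30L                                       # inside bc1
    lines <- c("@r1", rd1$seq, "+", intToPhred(rd1$qual),
               "@r2", rd2$seq, "+", intToPhred(rd2$qual),
               "@r3", paste(rep("ACGT", 20), collapse = ""), "+",
               strrep("~", 80))                              # unalignable
    fq <- file.path(dir, "t.fastq")
    writeLines(lines, fq)
    reads <- extractReads(fq, lay)
    d <- readData(reads)
    expect_equal(length(reads), 3L)
    expect_equal(d$keep, c(TRUE, FALSE, FALSE))
    expect_equal(d$dropReason, c("", "low_bc_qual", "unaligned"))
    expect_equal(d$virtualBarcode[1], "ACGTCATTGACA")
    expect_equal(d$minBcQual[2], 30L)
    ## serialization
    tsv <- file.path(dir, "ex.tsv")
    writeExtractions(reads, tsv)
    tab <- read.delim(tsv)
    expect_equal(nrow(tab), 3L)
    expect_equal(sort(tab$read_id), c("r1", "r2", "r3"))
})
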