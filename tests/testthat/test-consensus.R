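lay <- tinyLayout()
## tinyLayout ORF (ref 17..46): ATG CAT AAA ACT GTT TCC AGG CGA CGG TAA
##                protein:       M   H   K   T   V   S   R   R   R   *

test_that("consensus barcode is the plurality member with documented ties", {
    expect_equal(consensusBarcode(rep("ACGT", 3)), "ACGT")
    expect_equal(consensusBarcode(c(rep("AAAA", 5), "AAAT")), "AAAA")
    ## 2 vs 2 tie broken by total quality
    bcs <- c("AAAA", "AAAA", "CCCC", "CCCC")
    quals <- list(rep(50L, 4), rep(50L, 4), rep(90L, 4), rep(90L, 4))
    expect_equal(consensusBarcode(bcs, quals), "CCCC")
    ## full tie broken lexicographically
    expect_equal(consensusBarcode(c("TTTT", "AAAA")), "AAAA")
    ## result is always an observed barcode
    set.seed(8)
    for (rep in 1:20) {
        b <- replicate(sample(1:6, 1), randSeq(5))
        expect_true(consensusBarcode(b) %in% b)
    }
})

test_that("final genotype applies the error filter to the membership", {
    expect_equal(nrow(finalGenotype(rep(list(emptyVariants()), 4))), 0L)
    X <- variantTable(30, "A", "T", 93)
    Y <- variantTable(70, "C", "G", 20)
    g <- finalGenotype(c(rep(list(X), 3), list(Y)))
    expect_equal(variantKey(g), "30:A>T")
    ## singleton read with one high-quality variant is retained
    expect_equal(variantKey(finalGenotype(list(X))), "30:A>T")
})

test_that("single-codon consequences are classified correctly", {
    ## ATG -> ATA at codon 1: missense M1I (ref 19 G>A)
    tr <- translateVariants(variantTable(19, "G", "A", 93), lay)
    expect_equal(tr$type, "missense")
    expect_equal(tr$label, "p.M1I")
    ## third-position synonymous: CAT -> CAC (ref 22 T>C)
    tr2 <- translateVariants(variantTable(22, "T", "C", 93), lay)
    expect_equal(tr2$type, "synonymous")
    expect_equal(tr2$label, "p.H2=")
    ## nonsense: AAA -> TAA at codon 3 (ref 23 A>T)
    tr3 <- translateVariants(variantTable(23, "A", "T", 93), lay)
    expect_equal(tr3$type, "nonsense")
    expect_equal(tr3$label, "p.K3Ter")
    ## 1 bp deletion inside the ORF: frameshift
    tr4 <- translateVariants(variantTable(23, "A", "", 93), lay)
    expect_equal(tr4$type, "frameshift")
    expect_equal(tr4$label, "p.K3fs")
    ## in-frame 3 bp deletion
    tr5 <- translateVariants(variantTable(29, "GTT", "", 93), lay)
    expect_equal(tr5$type, "inframe_del")
    ## variant outside the ORF is non-coding
    tr6 <- translateVariants(variantTable(3, "T", "A", 93), lay)
    expect_equal(tr6$type, "noncoding")
})

test_that("same-codon substitutions are applied jointly", {
    ## codon 2 (CAT, ref 20..22): C>G and A>G together -> GGT = Gly
    v <- variantTable(c(20, 21), c("C", "A"), c("G", "G"), c(93, 93))
    tr <- translateVariants(v, lay)
    expect_equal(nrow(tr), 1L)
    expect_equal(tr$label, "p.H2G")
    ## an MNV spanning two codons affects both
    v2 <- variantTable(22, "TA", "AT", 93)     # codon2 pos3 + codon3 pos1
    tr2 <- translateVariants(v2, lay)
    expect_equal(nrow(tr2), 2L)
    expect_equal(tr2$codon, c(2L, 3L))
})

test_that("translation agrees with a full-ORF mutate-and-translate oracle", {
    lay2 <- exampleLayout()
    os <- IRanges::start(orfRange(lay2)); oe <- IRanges::end(orfRange(lay2))
    ref <- as.character(referenceSeq(lay2))
    refProt <- oracleTranslateORF(emptyVariants(), lay2)
    set.seed(77)
    for (rep in 1:200) {
        p <- sample(os:oe, 1)
        b <- substr(ref, p, p)
        alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        v <- variantTable(p, b, alt, 93L)
        tr <- translateVariants(v, lay2)
        mutProt <- oracleTranslateORF(v, lay2)
        diffs <- which(strsplit(refProt, "")[[1]] != strsplit(mutProt, "")[[1]])
        if (tr$type == "synonymous") {
            expect_equal(length(diffs), 0L)
        } else {
            expect_equal(length(diffs), 1L)
            expect_equal(diffs, tr$codon)
            aa <- substr(mutProt, diffs, diffs)
            if (tr$type == "nonsense") expect_equal(aa, "*")
            else expect_equal(substr(tr$label, nchar(tr$label), nchar(tr$label)), aa)
        }
    }
})

test_that("net frame annotation sums ORF indels modulo 3", {
    expect_equal(netFrameShift(emptyVariants(), lay), 0L)
    ins1 <- variantTable(25, "", "T", 93)
    del1 <- variantTable(35, "T", "", 93)
    expect_equal(netFrameShift(ins1, lay), 1L)
    expect_equal(netFrameShift(del1, lay), 2L)
    expect_equal(netFrameShift(rbind(ins1, del1), lay), 0L)
    ## non-ORF indels do not count
    expect_equal(netFrameShift(variantTable(2, "A", "", 93), lay), 0L)
})

test_that("homopolymer frameshift annotation needs run >= 4 and 5' position", {
    ref <- paste0("ACGTT", "AAA", "CG", "TTTT", "CA", "GGGGGGG", "ACGT")
    runs <- homopolymerRuns(ref, 4)
    expect_equal(runs$start, c(11L, 17L))       # TTTT and GGGGGGG only
    del1 <- function(p) variantTable(p, substr(ref, p, p), "", 93)
    ## 1 bp deletion at a run start, or immediately 5' of it
    expect_true(annotateHomopolymerFrameshift(del1(11), runs))
    expect_true(annotateHomopolymerFrameshift(del1(10), runs))
    expect_true(annotateHomopolymerFrameshift(del1(17), runs))
    ## run of length 3 never qualifies
    expect_false(annotateHomopolymerFrameshift(del1(6), runs))
    ## interior of a run is not the 5' end
    expect_false(annotateHomopolymerFrameshift(del1(13), runs))
    ## SNVs never qualify
    snv <- variantTable(11, "T", "A", 93)
    expect_false(annotateHomopolymerFrameshift(snv, runs))
    ## in-frame 3 bp deletion at a run start does not qualify
    del3 <- variantTable(17, "GGG", "", 93)
    expect_false(annotateHomopolymerFrameshift(del3, runs))
    ## frameshift-length insertion at the 5' end qualifies
    ins <- variantTable(10, "", "T", 93)
    expect_true(annotateHomopolymerFrameshift(ins, runs))
})

test_that("callClones assembles consensus barcodes, genotypes and consequences", {
    gX <- variantTable(19, "G", "A", 93)       # M1I
    rs <- readSet(sprintf("r%d", 1:6),
                  barcode1 = c(rep("ACGTCA", 5), "ACGACA"),
                  variants = rep(list(gX), 6),
                  barcode2 = rep("TTGACA", 6),
                  layout = lay)
    cs <- clusterReads(rs)
    calls <- callClones(cs)
    d <- callsTable(calls)
    expect_equal(nrow(d), 1L)
    expect_equal(d$barcode1, "ACGTCA")
    expect_equal(d$barcode2, "TTGACA")
    expect_equal(d$virtualBarcode, "ACGTCATTGACA")
    expect_equal(d$nReads, 6L)
    expect_equal(d$ntGenotype, "19:G>A:93")
    expect_equal(d$aaConsequences, "p.M1I")
    expect_false(d$homopolymerFs)
})
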