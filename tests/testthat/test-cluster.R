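test_that("edit distance agrees with a DP oracle", {
    expect_equal(barcodeEditDistance("ACGT", "ACGT"), 0L)
    expect_equal(barcodeEditDistance("ACGT", "AGT"), 1L)
    expect_equal(barcodeEditDistance("AAAA", "TTTT"), 4L)
    set.seed(17)
    for (rep in 1:40) {
        a <- randSeq(sample(4:12, 1)); b <- randSeq(sample(4:12, 1))
        expect_equal(barcodeEditDistance(a, b), oracleEditDistance(a, b))
    }
})

test_that("the error filter drops only single-read low-quality variants", {
    v <- function(pos, qual) variantTable(pos, "A", "T", qual)
    ## seen in 2 of 3 reads at low quality -> retained, qual = max support
    f1 <- filterVariantErrors(list(v(10, 20), v(10, 30), emptyVariants()), 50)
    expect_equal(variantKey(f1), "10:A>T")
    expect_equal(f1$qual, 30L)
    ## single read, low quality -> dropped
    expect_equal(nrow(filterVariantErrors(list(v(10, 49), emptyVariants()), 50)), 0L)
    ## single read, adequate quality -> retained
    expect_equal(variantKey(filterVariantErrors(list(v(10, 50)), 50)), "10:A>T")
    ## mixture: each variant judged on its own support
    mixed <- filterVariantErrors(list(
        rbind(v(10, 20), v(20, 90)), v(10, 25), v(30, 10)), 50)
    expect_setequal(variantKey(mixed), c("10:A>T", "20:A>T"))
})

test_that("Jaccard index on variant sets has the documented conventions", {
    a <- variantTable(c(10, 20), c("A", "C"), c("T", "G"), c(90, 90))
    b <- variantTable(c(10, 30, 40), c("A", "G", "T"), c("T", "A", "C"),
                      c(80, 80, 80))
    expect_equal(jaccardIndex(a, a), 1)
    expect_equal(jaccardIndex(emptyVariants(), emptyVariants()), 1)
    expect_equal(jaccardIndex(a, b), 0.25)      # |int|=1, |union|=4
    d <- variantTable(50, "A", "G", 90)
    expect_equal(jaccardIndex(a, d), 0)
})

test_that("seed clusters follow the WT/Jaccard edge rule", {
    wt <- emptyVariants()
    X <- variantTable(10, "A", "T", 93)
    Y <- variantTable(50, "C", "G", 93)
    ## three WT reads: one component
    expect_equal(seedClusters(list(wt, wt, wt)), list(1:3))
    ## {X},{X} vs disjoint {Y}: components of sizes 2 and 1
    comps <- seedClusters(list(X, X, Y))
    sizes <- sort(lengths(comps))
    expect_equal(sizes, c(1L, 2L))
    ## singleton input
    expect_equal(seedClusters(list(X)), list(1L))
    ## a WT read does not join a mutant read
    comps2 <- seedClusters(list(wt, X, X))
    expect_equal(sort(lengths(comps2)), c(1L, 2L))
})

test_that("size divergence uses |log2(size1/size2)| > ed strictly", {
    expect_true(sizeDivergenceOK(8, 1, 2))      # |log2 8| = 3 > 2
    expect_false(sizeDivergenceOK(4, 4, 1))     # 0 > 1 fails
    expect_true(sizeDivergenceOK(5, 1, 2))      # 2.32 > 2
    expect_false(sizeDivergenceOK(4, 1, 2))     # 2 > 2 fails (strict)
    expect_true(sizeDivergenceOK(1, 8, 2))      # symmetric
})

test_that("merge evaluation applies criteria a, b, c in order", {
    wt <- emptyVariants()
    ## 8 WT reads barcode B, 1 WT read at ED 1: accept
    bcs <- c(rep("AAAAAAAAA", 8), "AAAAAAAAT")
    vars <- rep(list(wt), 9)
    res <- evaluateMerge(1:8, 9L, 1L, bcs, vars)
    expect_true(res$accept)

    ## jaccard 1/9 < 0.2 with divergent sizes: reject on (a)
    gA <- variantTable(c(10, 20, 30, 40, 50), rep("A", 5), rep("T", 5), rep(93, 5))
    gB <- variantTable(c(10, 60, 70, 80, 90), rep("C", 5), rep("G", 5), rep(93, 5))
    gB$pos[1] <- 10; gB$ref[1] <- "A"; gB$alt[1] <- "T"    # one shared key
    bcs2 <- c(rep("AAAAAAAAA", 8), "AAAAAAAAT")
    vars2 <- c(rep(list(gA), 8), list(gB))
    res2 <- evaluateMerge(1:8, 9L, 1L, bcs2, vars2)
    expect_false(res2$accept)
    expect_equal(res2$reason, "a")

    ## equal sizes: reject on (c)
    res3 <- evaluateMerge(1:4, 5:8, 1L, rep(c("AAAAAAAAA", "AAAAAAAAT"),
                                            each = 4), rep(list(wt), 8))
    expect_false(res3$accept)
    expect_equal(res3$reason, "c")

    ## member pair beyond maxEd: reject on (b)
    bcs4 <- c(rep("AAAAAAAAA", 7), "AAAAAAGGG", "AAAAAAAAT")
    res4 <- evaluateMerge(1:8, 9L, 1L, bcs4, rep(list(wt), 9))
    expect_false(res4$accept)
    expect_equal(res4$reason, "b")
})

test_that("cluster_library merges satellites and keeps distinct clones apart", {
    wt <- emptyVariants()
    gX <- variantTable(30, "A", "T", 93)
    gY <- variantTable(80, "C", "G", 93)

    ## all reads identical barcode and genotype: one cluster
    rs <- readSet(sprintf("r%02d", 1:5), rep("ACGTACGTA", 5), rep(list(gX), 5))
    expect_equal(length(clusterReads(rs)), 1L)

    ## 10-read clone + 1 satellite at ED 1, same genotype: merged (11)
    rs2 <- readSet(sprintf("r%02d", 1:11),
                   c(rep("ACGTACGTA", 10), "ACGTACGTT"),
                   rep(list(gX), 11))
    cs2 <- clusterReads(rs2)
    expect_equal(length(cs2), 1L)
    expect_equal(clusterSizes(cs2), 11L)

    ## two 6-read clones at barcode ED 1 with different genotypes: separate
    rs3 <- readSet(sprintf("r%02d", 1:12),
                   rep(c("ACGTACGTA", "ACGTACGTT"), each = 6),
                   c(rep(list(gX), 6), rep(list(gY), 6)))
    cs3 <- clusterReads(rs3)
    expect_equal(length(cs3), 2L)
    expect_equal(sort(clusterSizes(cs3)), c(6L, 6L))
})

test_that("clustering invariants hold on random micro-libraries", {
    for (seed in 101:110) {
        ml <- makeMicroLibrary(seed)
        rs <- readSet(ml$readId, ml$barcode, ml$varList)
        cs <- clusterReads(rs)
        ## partition: every kept read in exactly one cluster
        mem <- sort(unlist(lapply(cloneClusters(cs), `[[`, "members")))
        expect_equal(mem, seq_along(ml$readId))
        ## criterion-b guarantee on every final cluster
        for (cl in cloneClusters(cs)) {
            ub <- unique(ml$barcode[cl$members])
            if (length(ub) > 1) expect_lte(max(utils::adist(ub)), 2)
        }
        ## maxEd = 0 reproduces the identical-barcode seed clustering
        cs0 <- clusterReads(rs, maxEd = 0L)
        for (cl in cloneClusters(cs0))
            expect_equal(length(unique(ml$barcode[cl$members])), 1L)
        seedsOnly <- unlist(lapply(split(seq_along(ml$barcode), ml$barcode),
            function(idx) lapply(seedClusters(ml$varList[idx]),
                                 function(s) sort(idx[s]))), recursive = FALSE)
        got0 <- lapply(cloneClusters(cs0), function(cl) sort(cl$members))
        expect_setequal(lapply(got0, paste, collapse = ","),
                        lapply(seedsOnly, paste, collapse = ","))
    }
})

test_that("optimized clustering equals the brute-force reference", {
    for (seed in 201:215) {
        ml <- makeMicroLibrary(seed)
        rs <- readSet(ml$readId, ml$barcode, ml$varList)
        got <- packagePartition(clusterReads(rs))
        want <- oracleClusterLibrary(ml$readId, ml$barcode, ml$varList,
                                     qualTotal = 93 * nchar(ml$barcode))
        expect_equal(got, want, info = paste("seed", seed))
    }
})
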