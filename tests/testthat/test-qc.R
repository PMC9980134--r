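test_that("uniqueness classification applies the strict two-thirds rule", {
    calls <- makeCalls(
        barcode1 = c("AAAAAA", "CCCCCC", "CCCCCC", "GGGGGG", "GGGGGG"),
        barcode2 = c("TTTTTT", "TGTGTG", "ACACAC", "TCTCTC", "AGAGAG"),
        nReads = c(7, 10, 2, 8, 4),
        genotypes = c("", "30:A>T:93", "", "25:C>G:93", "40:G>A:93"))
    ## key on upstream so the three barcodes form three groups
    u <- classifyBarcodeUniqueness(calls, key = "upstream")
    u <- u[order(u$barcode), ]
    expect_equal(u$status[u$barcode == "AAAAAA"], "unique")
    ## 10 vs 2: 10 > (2/3)*12 = 8 -> remediable
    expect_equal(u$status[u$barcode == "CCCCCC"], "non_unique_remediable")
    ## 8 vs 4: 8 = (2/3)*12 exactly, strict ">" -> non_unique
    expect_equal(u$status[u$barcode == "GGGGGG"], "non_unique")
    ## statuses partition the groups
    expect_true(all(u$status %in% c("unique", "non_unique",
                                    "non_unique_remediable")))
    ## keyed on virtual barcode every group here is unique
    uv <- classifyBarcodeUniqueness(calls, key = "virtual")
    expect_true(all(uv$status == "unique"))
})

test_that("chimera detection requires dual barcodes and genotype overlap", {
    ## two clones, same upstream, identical genotype, very different
    ## downstream: one complete-evidence set
    calls <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "GGGGGG"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93"))
    ch <- detectChimeras(calls, direction = "upstream")
    expect_equal(length(unique(ch$setId)), 1L)
    expect_equal(unique(ch$evidence), "complete")
    expect_setequal(ch$otherBarcode, c("CCCCCC", "GGGGGG"))

    ## disjoint genotypes: no chimera evidence
    calls2 <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "GGGGGG"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "40:C>G:93"))
    expect_equal(nrow(detectChimeras(calls2, direction = "upstream")), 0L)

    ## same downstream barcode (would have been clustered): no set
    calls3 <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "CCCCCC"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93"))
    expect_equal(nrow(detectChimeras(calls3, direction = "upstream")), 0L)

    ## downstream within maxEd is not "entirely different"
    calls4 <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "CCCCCA"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93"))
    expect_equal(nrow(detectChimeras(calls4, maxEd = 2, direction = "upstream")), 0L)

    ## partial overlap (non-empty intersection) counts
    calls5 <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "GGGGGG"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93,40:C>G:93", "30:A>T:93,55:G>A:93"))
    ch5 <- detectChimeras(calls5, direction = "upstream")
    expect_equal(unique(ch5$evidence), "partial")

    ## two WT clones are flagged but annotated wt_only
    calls6 <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA"),
        barcode2 = c("CCCCCC", "GGGGGG"),
        nReads = c(5, 5), genotypes = c("", ""))
    ch6 <- detectChimeras(calls6, direction = "upstream")
    expect_equal(unique(ch6$evidence), "wt_only")

    ## downstream anchoring finds the symmetric case
    calls7 <- makeCalls(
        barcode1 = c("AAAAAA", "GGGGGG"),
        barcode2 = c("CCCCCC", "CCCCCC"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93"))
    expect_equal(nrow(detectChimeras(calls7, direction = "upstream")), 0L)
    ch7 <- detectChimeras(calls7, direction = "both")
    expect_equal(unique(ch7$direction), "downstream")

    ## single-barcode layout: explicit error, not a silent no-op
    single <- makeCalls(barcode1 = c("AAAAAA", "AAAAAA"), nReads = c(5, 5),
                        genotypes = c("", ""))
    expect_error(detectChimeras(single), "dual-barcode")
})

test_that("chimera sets are maximal under transitive closure", {
    ## three clones sharing an upstream barcode: A-B overlap, B-C overlap,
    ## A-C disjoint; all pairwise-different downstream -> one set of 3
    calls <- makeCalls(
        barcode1 = rep("AAAAAA", 3),
        barcode2 = c("CCCCCC", "GGGGGG", "TTTTTT"),
        nReads = c(5, 5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93,50:C>G:93", "50:C>G:93"))
    ch <- detectChimeras(calls, direction = "upstream")
    expect_equal(length(unique(ch$setId)), 1L)
    expect_equal(nrow(ch), 3L)
})

test_that("flags propagate into clone calls", {
    calls <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA", "GGGGGG"),
        barcode2 = c("CCCCCC", "TTTTTT", "ACACAC"),
        nReads = c(10, 2, 5),
        genotypes = c("30:A>T:93", "30:A>T:93", ""))
    uniq <- classifyBarcodeUniqueness(calls, key = "upstream")
    ## virtual-keyed flags: all virtual barcodes are distinct -> no non_unique
    uv <- classifyBarcodeUniqueness(calls, key = "virtual")
    chim <- detectChimeras(calls, direction = "upstream")
    flagged <- flagCloneCalls(calls, uv, chim)
    f <- callsTable(flagged)$flags
    expect_true(grepl("chimera_suspect", f[1]))
    expect_true(grepl("chimera_suspect", f[2]))
    expect_equal(f[3], "")
})

test_that("cross-tabulation counts upstream barcodes by both flags", {
    ## one upstream barcode chimera-involved; uniqueness from an
    ## upstream-only view where it is also non-unique
    calls <- makeCalls(
        barcode1 = c("AAAAAA", "AAAAAA", "GGGGGG"),
        barcode2 = c("CCCCCC", "TTTTTT", "ACACAC"),
        nReads = c(10, 5, 5),
        genotypes = c("30:A>T:93", "30:A>T:93", ""))
    ct <- crossTabulateChimeraFlags(calls)
    expect_equal(as.vector(ct$table["TRUE", "TRUE"]), 1L)
    expect_equal(as.vector(ct$table["FALSE", "FALSE"]), 1L)
    expect_equal(ct$pNonUniqueGivenChimera, 1)
    expect_equal(ct$pChimeraGivenNonUnique, 1)

    ## no chimeras, no non-unique: only the (no, no) cell is filled
    calls2 <- makeCalls(
        barcode1 = c("AAAAAA", "GGGGGG"),
        barcode2 = c("CCCCCC", "TTTTTT"),
        nReads = c(5, 5),
        genotypes = c("30:A>T:93", "40:C>G:93"))
    ct2 <- crossTabulateChimeraFlags(calls2)
    expect_equal(sum(ct2$table), 2L)
    expect_equal(as.vector(ct2$table["FALSE", "FALSE"]), 2L)
})
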