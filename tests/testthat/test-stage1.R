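toyIndex <- function() {
    buildFeatureIndex(makeAnnotation(list(
        A = list(TA = list(c(101, 300))),
        B = list(TB = list(c(251, 450))),
        C = list(TC = list(c(1001, 1400))))))
}

test_that("per-mate gene sets implement the three overlap modes", {
    idx <- toyIndex()
    # fully inside A
    s <- mateGeneSets(idx, "chr1", 120L, "100M")
    expect_equal(s$union, "A")
    expect_equal(s$intersection_strict, "A")
    expect_equal(s$intersection_nonempty, "A")
    # half in A, half outside any feature: strict loses A, nonempty keeps it
    s <- mateGeneSets(idx, "chr1", 51L, "100M")
    expect_equal(s$union, "A")
    expect_equal(s$intersection_strict, character(0))
    expect_equal(s$intersection_nonempty, "A")
    # every base under both A and B
    s <- mateGeneSets(idx, "chr1", 251L, "50M")
    expect_equal(s$union, c("A", "B"))
    expect_equal(s$intersection_strict, c("A", "B"))
    expect_equal(s$intersection_nonempty, c("A", "B"))
})

test_that("cigar operations are honoured in per-base sets", {
    idx <- toyIndex()
    # N skips the A/B overlap zone entirely: 50M200N50M from 151 covers
    # 151-200 (A only) and 401-450 (B only)
    s <- mateGeneSets(idx, "chr1", 151L, "50M200N50M")
    expect_equal(s$union, c("A", "B"))
    expect_equal(s$intersection_strict, character(0))
    expect_equal(s$intersection_nonempty, character(0))
    # D consumes reference: 50M10D40M spans 100 reference bases
    s <- mateGeneSets(idx, "chr1", 201L, "50M10D40M")
    expect_equal(s$union, c("A", "B"))
    # I and S consume none
    s2 <- mateGeneSets(idx, "chr1", 120L, "5S50M10I50M")
    expect_equal(s2$intersection_strict, "A")
})

test_that("fragment verdicts follow mode and multi-mapping rules", {
    idx <- toyIndex()
    # unique pair fully inside A
    fr <- makeFragments(data.table(
        qname = "f1", mate = 1:2, rname = "chr1", pos = c(110L, 150L),
        cigar = "100M", nh = 1L))
    for (m in c("union", "intersection_strict", "intersection_nonempty")) {
        fates <- fragmentFates(resolveFragments(fr, idx, m))
        expect_equal(as.character(fates$verdict), "assigned")
        expect_equal(fates$gene_id, "A")
    }
    # NH = 2 is alignment_not_unique regardless of overlap
    fr <- makeFragments(data.table(
        qname = "f2", mate = c(1L, 2L, 1L, 2L),
        rname = "chr1", pos = c(110L, 150L, 1010L, 1080L),
        cigar = "100M", nh = 2L))
    fates <- fragmentFates(resolveFragments(fr, idx, "union"))
    expect_equal(as.character(fates$verdict), "alignment_not_unique")
    expect_equal(fates$mmg, "A|C")
    # mate1 in A only, mate2 in C only, union mode: ambiguous
    fr <- makeFragments(data.table(
        qname = "f3", mate = 1:2, rname = "chr1", pos = c(110L, 1010L),
        cigar = "100M", nh = 1L))
    fates <- fragmentFates(resolveFragments(fr, idx, "union"))
    expect_equal(as.character(fates$verdict), "ambiguous")
    # intronic/intergenic unique fragment: no_feature, no MMG genes
    fr <- makeFragments(data.table(
        qname = "f4", mate = 1:2, rname = "chr1", pos = c(501L, 651L),
        cigar = "100M", nh = 1L))
    fates <- fragmentFates(resolveFragments(fr, idx, "union"))
    expect_equal(as.character(fates$verdict), "no_feature")
    expect_equal(fates$mmg, "")
})

test_that("stage-1 counts recover simulated truth on unique genes", {
    ds <- simulateDataset(simDesign(8, pairsPerGene = 100, seed = 6))
    idx <- buildFeatureIndex(ds@annotation)
    fr <- truthAlign(ds)
    for (m in c("union", "intersection_strict", "intersection_nonempty")) {
        res <- countStage1(fr, idx, m)
        expect_equal(unname(geneCounts(res)[simTruth(ds)$gene_id]),
                     simTruth(ds)$true_count)
        expect_equal(unname(fateTallies(res)["assigned"]), 800L)
    }
})

test_that("an identical two-gene family zeroes stage-1 counts", {
    ds <- simulateDataset(simDesign(0, pairsPerGene = 100,
        familySpec = data.frame(size = 2, divergence = 0), seed = 8))
    idx <- buildFeatureIndex(ds@annotation)
    res <- countStage1(truthAlign(ds), idx, "union")
    expect_equal(unname(geneCounts(res)), c(0L, 0L))
    expect_equal(unname(fateTallies(res)["alignment_not_unique"]), 200L)
})

test_that("empty input yields empty tallies", {
    idx <- toyIndex()
    fr <- makeFragments(data.table(qname = character(), mate = integer(),
                                   rname = character(), pos = integer(),
                                   cigar = character(), nh = integer()))
    res <- countStage1(fr, idx, "union")
    expect_true(all(fateTallies(res) == 0L))
    expect_true(all(geneCounts(res) == 0L))
})

test_that("fates conserve fragments and strict assignments nest in nonempty", {
    set.seed(77)
    ann <- makeAnnotation(list(
        A = list(TA = list(c(101, 400))),
        B = list(TB = list(c(351, 700))),
        C = list(TC = list(c(1001, 1300)))))
    idx <- buildFeatureIndex(ann)
    for (rep in 1:10) {
        n <- 60
        dt <- data.table(
            qname = rep(sprintf("f%03d", 1:n), each = 2),
            mate = rep(1:2, n), rname = "chr1",
            pos = sample(1:1400, 2 * n, replace = TRUE),
            cigar = "80M",
            nh = rep(sample(c(1L, 1L, 1L, 2L), n, replace = TRUE), each = 2))
        fr <- makeFragments(dt)
        res <- lapply(c("union", "intersection_strict",
                        "intersection_nonempty"),
                      function(m) resolveFragments(fr, idx, m))
        for (r in res)
            expect_equal(sum(fateTallies(r)), nFragments(fr))
        fs <- lapply(res, function(r) as.data.table(
            as.data.frame(fragmentFates(r))))
        strictA <- fs[[2]][verdict == "assigned"]
        neA <- fs[[3]][verdict == "assigned"]
        expect_true(all(strictA$fragment_id %in% neA$fragment_id))
        both <- merge(strictA[, .(fragment_id, g1 = gene_id)],
                      neA[, .(fragment_id, g2 = gene_id)],
                      by = "fragment_id")
        expect_true(all(both$g1 == both$g2))
    }
})

test_that("stranded counting discards antisense fragments", {
    ann <- makeAnnotation(list(A = list(TA = list(c(101, 400)))),
                          strand = "+")
    idx <- buildFeatureIndex(ann)
    # proper FR pair from the + strand: mate1 +, mate2 -
    sense <- makeFragments(data.table(
        qname = "s", mate = 1:2, rname = "chr1", pos = c(110L, 260L),
        cigar = "100M", nh = 1L, strand = c("+", "-")))
    anti <- makeFragments(data.table(
        qname = "a", mate = 1:2, rname = "chr1", pos = c(260L, 110L),
        cigar = "100M", nh = 1L, strand = c("-", "+")))
    expect_equal(unname(geneCounts(resolveFragments(sense, idx, "union",
                                                    stranded = "yes"))), 1L)
    expect_equal(unname(geneCounts(resolveFragments(anti, idx, "union",
                                                    stranded = "yes"))), 0L)
    expect_equal(unname(geneCounts(resolveFragments(anti, idx, "union",
                                                    stranded = "reverse"))), 1L)
    expect_equal(unname(geneCounts(resolveFragments(anti, idx, "union",
                                                    stranded = "no"))), 1L)
})
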