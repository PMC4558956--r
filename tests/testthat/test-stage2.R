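test_that("group ids are canonical set serialisations", {
    expect_equal(mmgId(c("B", "A", "B")), "A|B")
    expect_equal(mmgId("Z"), "Z")
    expect_equal(mmgId(character(0)), "")
})

test_that("unassigned fragments map to the union of their loci's genes", {
    idx <- buildFeatureIndex(makeAnnotation(list(
        A = list(TA = list(c(101, 400))),
        B = list(TB = list(c(1001, 1300))))))
    frags <- makeFragments(data.table(
        qname = c("m1", "m1", "m2", "m2", "m3", "m3"),
        mate = 1L, rname = "chr1",
        pos = c(110L, 1010L,   # loci over A and B -> {A,B}
                120L, 210L,    # both loci over A -> {A}, size 1
                130L, 601L),   # one locus over A, one intergenic -> {A}
        cigar = "50M", nh = 2L))
    res <- resolveFragments(frags, idx, "union")
    g <- fragmentGroups(res)
    expect_equal(g[qname == "m1", group], "A|B")
    expect_equal(g[qname == "m2", group], "A")
    expect_equal(g[qname == "m3", group], "A")
})

test_that("each rescuable fragment lands in exactly one group per sample", {
    ds <- simulateDataset(simDesign(2, pairsPerGene = 50,
        familySpec = data.frame(size = 2, divergence = 0), seed = 12))
    idx <- buildFeatureIndex(ds@annotation)
    res <- countStage1(truthAlign(ds), idx, "union")
    se <- countMmgs(list(s1 = res))
    a <- assay(se, "counts")
    expect_equal(sum(a), unname(fateTallies(res)["alignment_not_unique"]))
    expect_equal(rownames(a), "FAM1_1|FAM1_2")
    expect_equal(sum(a), 100L)
})

test_that("distinct gene sets stay distinct at counting time", {
    mkRes <- function(groups) {
        f <- data.table(fragment_id = seq_along(groups),
                        qname = paste0("q", seq_along(groups)),
                        verdict = factor("alignment_not_unique",
                                         levels = MMGcount:::.VERDICTS),
                        gene_id = NA_character_, mmg = groups)
        new("Stage1Results", counts = c(A = 0L), fates = S4Vectors::DataFrame(f),
            tallies = setNames(c(0L, 0L, 0L, length(groups), 0L),
                               MMGcount:::.VERDICTS), mode = "union")
    }
    se <- countMmgs(list(s1 = mkRes(c(rep("A|B", 3), rep("A|B|C", 2)))))
    a <- assay(se, "counts")
    expect_equal(dim(a), c(2L, 1L))
    expect_equal(a["A|B", "s1"], 3L)
    expect_equal(a["A|B|C", "s1"], 2L)

    # two samples with disjoint groups: zeros off the diagonal
    se2 <- countMmgs(list(s1 = mkRes(rep("A|B", 2)),
                          s2 = mkRes(rep("C|D", 4))))
    a2 <- assay(se2, "counts")
    expect_equal(a2["A|B", ], c(s1 = 2L, s2 = 0L))
    expect_equal(a2["C|D", ], c(s1 = 0L, s2 = 4L))
})

test_that("the support filter applies >= thresholds on reads and samples", {
    n <- 27
    m <- rbind(keep13 = c(rep(100L, 13), rep(0L, n - 13)),
               all99 = rep(99L, n),
               only12 = c(rep(150L, 12), rep(0L, n - 12)))
    colnames(m) <- paste0("s", 1:n)
    se <- mmgFromMatrix(m)
    kept <- filterMmgs(se, minReads = 100, minSamples = 13)
    expect_equal(rownames(kept), "keep13")
    expect_error(filterMmgs(se, minSamples = 28), "exceeds")
})

test_that("collapse merges contained large groups and conserves counts", {
    m <- rbind("A|B|C|D|E" = c(10L, 20L),
               "A|B|C|D|E|F" = c(1L, 2L),
               "A|B|C|D" = c(5L, 5L),
               "F|G|H|I|J" = c(7L, 7L))
    colnames(m) <- c("s1", "s2")
    out <- assay(collapseMmgs(mmgFromMatrix(m), minSize = 5), "counts")
    # the contained 5-set merged into its 6-superset; the 4-set is too small
    expect_false("A|B|C|D|E" %in% rownames(out))
    expect_equal(out["A|B|C|D|E|F", ], c(s1 = 11L, s2 = 22L))
    expect_equal(out["A|B|C|D", ], c(s1 = 5L, s2 = 5L))
    expect_equal(out["F|G|H|I|J", ], c(s1 = 7L, s2 = 7L))
    expect_equal(colSums(out), colSums(m))
})

test_that("collapse and filter agree with brute-force implementations", {
    set.seed(202)
    for (rep in 1:300) {
        m <- randomMmgMatrix(sample(2:12, 1), sample(1:27, 1))
        minReads <- sample(c(1L, 50L, 100L), 1)
        minSamples <- sample(seq_len(ncol(m)), 1)
        f1 <- assay(filterMmgs(mmgFromMatrix(m), minReads, minSamples),
                    "counts")
        f2 <- naiveFilterMmgs(m, minReads, minSamples)
        expect_identical(f1, f2)
        c1 <- assay(collapseMmgs(mmgFromMatrix(m), 5L), "counts")
        c2 <- naiveCollapseMmgs(m, 5L)
        expect_identical(c1[order(rownames(c1)), , drop = FALSE],
                         c2[order(rownames(c2)), , drop = FALSE])
        # idempotence and conservation
        c3 <- assay(collapseMmgs(mmgFromMatrix(c1), 5L), "counts")
        expect_identical(c3[order(rownames(c3)), , drop = FALSE],
                         c1[order(rownames(c1)), , drop = FALSE])
        expect_equal(colSums(c1), colSums(m))
    }
})

test_that("rescue statistics report the recovered share of discarded reads", {
    ds <- simulateDataset(simDesign(0, pairsPerGene = 1000,
        familySpec = data.frame(size = 2, divergence = 0), seed = 14))
    idx <- buildFeatureIndex(ds@annotation)
    res <- countStage1(truthAlign(ds), idx, "union")
    se <- collapseMmgs(filterMmgs(countMmgs(list(s1 = res)),
                                  minReads = 100, minSamples = 1))
    rs <- rescueStats(list(s1 = res), se)
    # every fragment is multi-mapped; all are rescued into the family MMG
    expect_equal(rs$unassigned_pct, 100)
    expect_equal(rs$rescued_pct, 100)
    expect_equal(assay(se, "counts")["FAM1_1|FAM1_2", "s1"], 2000L)
})

test_that("rescue is undefined, not an error, with nothing to rescue", {
    ds <- simulateDataset(simDesign(3, pairsPerGene = 20, seed = 15))
    idx <- buildFeatureIndex(ds@annotation)
    res <- countStage1(truthAlign(ds), idx, "union")
    se <- countMmgs(list(s1 = res))
    rs <- rescueStats(list(s1 = res), se)
    expect_true(is.na(rs$rescued_pct))
    expect_equal(rs$unassigned, 0L)
})

test_that("size-1 groups are reportable separately", {
    m <- rbind("A" = c(5L), "A|B" = c(7L))
    colnames(m) <- "s1"
    se <- mmgFromMatrix(m)
    expect_equal(rownames(singletonMmgs(se)), "A")
})
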