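test_that("design invariants are enforced", {
    expect_error(simDesign(5, insertLen = 90, readLen = 100), "insertLen")
    expect_error(simDesign(5, minTranscriptLen = 200), "minTranscriptLen")
    expect_error(simDesign(5, familySpec = data.frame(size = 2,
                                                      divergence = 1.5)),
                 "divergence")
})

test_that("forced geometry: transcript length equal to insert", {
    tx <- paste(sample(c("A", "C", "G", "T"), 250, replace = TRUE),
                collapse = "")
    p <- simulatePairs(tx, 5, readLen = 100, insertLen = 250)
    expect_true(all(p$start == 1L))
    expect_equal(as.character(p$mate1),
                 rep(substr(tx, 1, 100), 5), ignore_attr = TRUE)
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(substr(tx, 151, 250))))
    expect_equal(as.character(p$mate2), rep(rc, 5), ignore_attr = TRUE)
})

test_that("degenerate pair requests are handled", {
    tx <- strrep("ACGT", 100)
    p <- simulatePairs(tx, 0)
    expect_equal(length(p$mate1), 0L)
    expect_error(simulatePairs(strrep("ACGT", 50), 1),
                 "shorter than insert")
})

test_that("unique genes share no read-length k-mer; identical families do", {
    ds <- generateTranscriptome(simDesign(10, seed = 2))
    expect_equal(sharedKmers(ds@transcripts, 100L), 0L)
    fam <- generateTranscriptome(simDesign(0,
        familySpec = data.frame(size = 2, divergence = 0), seed = 2))
    expect_equal(as.character(fam@transcripts[[1]]),
                 as.character(fam@transcripts[[2]]))
    expect_gt(sharedKmers(fam@transcripts, 100L), 0L)
})

test_that("divergent family members drift apart at the k-mer level", {
    fam <- generateTranscriptome(simDesign(0,
        familySpec = data.frame(size = 3, divergence = 0.5), seed = 9))
    expect_equal(sharedKmers(fam@transcripts, 100L), 0L)
})

test_that("count draws respect fixed and ranged designs", {
    fixed <- simulateDataset(simDesign(7, pairsPerGene = 1000, seed = 3),
                             countOnly = TRUE)
    expect_true(all(simTruth(fixed)$true_count == 1000L))
    rng <- simulateDataset(simDesign(50, pairsPerGene = c(100L, 100000L),
                                     seed = 3), countOnly = TRUE)
    cnt <- simTruth(rng)$true_count
    expect_true(all(cnt >= 100L & cnt <= 100000L))
    expect_gt(length(unique(cnt)), 10L)
})

test_that("identical seeds give byte-identical FASTQ and SAM", {
    gen <- function() {
        ds <- simulateDataset(simDesign(4, pairsPerGene = 25,
            familySpec = data.frame(size = 2, divergence = 0), seed = 13))
        fq1 <- tempfile(); sam <- tempfile()
        writeFastq(ds@reads$mate1, fq1)
        writeSam(truthAlign(ds), sam,
                 setNames(width(ds@genome), names(ds@genome)),
                 seqs = ds@reads)
        list(fq = readLines(fq1), sam = readLines(sam))
    }
    a <- gen(); b <- gen()
    expect_identical(a$fq, b$fq)
    expect_identical(a$sam, b$sam)
})

test_that("truth aligner is conservative and complete", {
    ds <- simulateDataset(simDesign(3, pairsPerGene = 20,
        familySpec = data.frame(size = 2, divergence = 0), seed = 21))
    fr <- truthAlign(ds)
    # conservation: one fragment per simulated pair
    expect_equal(nFragments(fr), sum(simTruth(ds)$true_count))
    # completeness: loci of each mate equal a naive all-positions scan
    g <- as.character(ds@genome[[1]])
    rec <- fr@records
    qs <- sample(unique(rec$qname), 15)
    for (q in qs) {
        for (m in 1:2) {
            read <- as.character(ds@reads[[paste0("mate", m)]][[q]])
            naive <- naiveLoci(read, g)
            got <- rec[qname == q & mate == m]
            expect_setequal(got[strand == "+", pos], naive$fw)
            expect_setequal(got[strand == "-", pos], naive$rv)
        }
    }
})

test_that("k identical family members force exactly k loci per read", {
    for (k in 2:3) {
        ds <- simulateDataset(simDesign(1, pairsPerGene = 15,
            familySpec = data.frame(size = k, divergence = 0),
            seed = 30 + k))
        fr <- truthAlign(ds)
        fam <- simTruth(ds)$gene_id[startsWith(simTruth(ds)$gene_id, "FAM")]
        org <- ds@reads$origins
        famQ <- org[gene_id %in% fam, qname]
        rec <- fr@records
        expect_true(all(rec[qname %in% famQ, nh] == k))
        expect_true(all(rec[!qname %in% famQ, nh] == 1L))
    }
})

test_that("intron-aware embedding lifts reads to spliced coordinates", {
    ds <- simulateDataset(simDesign(3, pairsPerGene = 30, intronLen = 80,
                                    exonsPerTranscript = 3, seed = 17))
    fr <- truthAlign(ds)
    expect_true(any(grepl("N", fr@records$cigar)))
    # aligned sequence reassembled from the genome equals the read
    g <- as.character(ds@genome[[1]])
    rec <- fr@records[grepl("N", cigar)][1:10]
    for (i in seq_len(nrow(rec))) {
        r <- rec[i]
        blocks <- MMGcount:::.recordBlocks(r)
        pieces <- substring(g, blocks$start, blocks$end)
        spliced <- paste(pieces, collapse = "")
        read <- as.character(ds@reads[[paste0("mate", r$mate)]][[r$qname]])
        if (r$strand == "-")
            read <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(read)))
        expect_equal(spliced, read)
    }
    # and stage-1 counting still recovers the truth
    idx <- buildFeatureIndex(ds@annotation)
    res <- countStage1(fr, idx, "union")
    expect_equal(unname(geneCounts(res)[simTruth(ds)$gene_id]),
                 simTruth(ds)$true_count)
})

test_that("expected FPKM in the truth table follows the count formula", {
    ds <- simulateDataset(simDesign(6, pairsPerGene = 500, seed = 4),
                          countOnly = TRUE)
    tr <- simTruth(ds)
    rm <- sum(tr$true_count) / 1e6
    expect_equal(tr$expected_fpkm,
                 (tr$true_count / (tr$length_bp / 1000)) / rm)
    et <- expectedFpkmTable(ds)
    expect_equal(et$expected_fpkm, tr$expected_fpkm)
})
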