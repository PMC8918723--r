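library(data.table)

test_that("duplicate fragments collapse by coordinate-strand key", {
  # three PE fragments, two sharing (chrT, 100, 250, OT)
  aln <- rbindlist(list(
    makeAln("chrT", 100, strrep("A", 50), "OT", mate = 1, fragment_id = 1,
            frag_start = 100, frag_end = 250),
    makeAln("chrT", 200, strrep("A", 50), "OT", mate = 2, fragment_id = 1,
            frag_start = 100, frag_end = 250),
    makeAln("chrT", 100, strrep("A", 50), "OT", mate = 1, fragment_id = 2,
            frag_start = 100, frag_end = 250,
            qual_w = strrep("#", 50)),
    makeAln("chrT", 200, strrep("A", 50), "OT", mate = 2, fragment_id = 2,
            frag_start = 100, frag_end = 250,
            qual_w = strrep("#", 50)),
    makeAln("chrT", 300, strrep("A", 50), "OT", mate = 1, fragment_id = 3,
            frag_start = 300, frag_end = 420),
    makeAln("chrT", 370, strrep("A", 50), "OT", mate = 2, fragment_id = 3,
            frag_start = 300, frag_end = 420)))
  dd <- dedupAlignments(sortAln(aln))
  expect_identical(dd$stats$input_alignments, 3L)
  expect_identical(dd$stats$duplicates_removed, 1L)
  expect_identical(dd$stats$reported, 2L)
  # the higher-quality copy (fragment 1) survives
  expect_true(1L %in% dd$alignments$fragment_id)
  expect_false(2L %in% dd$alignments$fragment_id)

  # identical coordinates but opposite bisulfite strand: both kept
  aln2 <- rbindlist(list(
    makeAln("chrT", 100, strrep("A", 50), "OT", fragment_id = 1,
            frag_start = 100, frag_end = 250),
    makeAln("chrT", 100, strrep("A", 50), "OB", fragment_id = 2,
            frag_start = 100, frag_end = 250)))
  dd2 <- dedupAlignments(sortAln(aln2))
  expect_identical(dd2$stats$duplicates_removed, 0L)
})

test_that("dedup removes exactly sum(k-1) over constructed multiplicities", {
  set.seed(77)
  ks <- sample(1:5, 100, replace = TRUE)
  rows <- list()
  fid <- 0L
  for (i in seq_along(ks)) {
    start <- 1000L + i * 211L
    for (k in seq_len(ks[i])) {
      fid <- fid + 1L
      rows[[length(rows) + 1L]] <-
        makeAln("chr1", start, strrep("A", 60), "OT", mate = 1,
                fragment_id = fid, frag_start = start,
                frag_end = start + 160L)
      rows[[length(rows) + 1L]] <-
        makeAln("chr1", start + 100L, strrep("A", 60), "OT", mate = 2,
                fragment_id = fid, frag_start = start,
                frag_end = start + 160L)
    }
  }
  aln <- sortAln(rbindlist(rows))
  dd <- dedupAlignments(aln)
  expect_identical(dd$stats$duplicates_removed, sum(ks - 1L))
  expect_identical(dd$stats$reported, length(ks))
  # idempotence
  dd2 <- dedupAlignments(dd$alignments)
  expect_identical(dd2$stats$duplicates_removed, 0L)
  expect_identical(dd2$alignments, dd$alignments)
})

test_that("unsorted alignment input is fatal", {
  aln <- rbindlist(list(
    makeAln("chr1", 500, "ACGT", "OT", fragment_id = 1),
    makeAln("chr1", 100, "ACGT", "OT", fragment_id = 2)))
  expect_error(dedupAlignments(aln), "sorted")
})

# a 9-bp genome with one CpG at 0-based position 4: AAT TCG TAA
cpgRef <- ReferenceGenome(c(chrT = "AATTCGTAA"), spikeIns = character(0))
cpgIdx <- buildCpGIndex(cpgRef)

test_that("per-CpG counting follows bisulfite semantics and inverts for TAPS", {
  # three OT reads covering the CpG: pileup {C, C, T} at the Watson C
  aln <- rbindlist(lapply(1:3, function(i)
    makeAln("chrT", 2, paste0("TT", c("C", "C", "T")[i], "GT"), "OT",
            fragment_id = i)))
  aln <- sortAln(aln)
  bs <- callCpGs(aln, cpgRef, cpgIdx, "bisulfite")
  expect_identical(nrow(bs), 1L)
  expect_identical(bs$pos, 4L)
  expect_identical(bs$meth, 2L)
  expect_identical(bs$unmeth, 1L)
  expect_equal(bs$beta, 2 / 3, tolerance = 1e-12)
  tp <- callCpGs(aln, cpgRef, cpgIdx, "taps")
  expect_identical(tp$meth, 1L)
  expect_identical(tp$unmeth, 2L)
  expect_equal(tp$beta, 1 / 3, tolerance = 1e-12)
  expect_error(callCpGs(aln, cpgRef, cpgIdx), "chemistry")
})

test_that("strand-resolved counts separate OT and OB observations", {
  # one OT read showing C at the Watson C, one OB read showing A at the
  # Watson G (i.e. converted Crick C)
  aln <- rbindlist(list(
    makeAln("chrT", 2, "TTCGT", "OT", fragment_id = 1),
    makeAln("chrT", 2, "TTCAT", "OB", fragment_id = 2)))
  aln <- sortAln(aln)
  bs <- callCpGs(aln, cpgRef, cpgIdx, "bisulfite")
  expect_identical(bs$meth, 1L)
  expect_identical(bs$unmeth, 1L)
  expect_identical(bs$meth_watson, 1L)
  expect_identical(bs$unmeth_watson, 0L)
  expect_identical(bs$meth_crick, 0L)
  expect_identical(bs$unmeth_crick, 1L)
  expect_identical(bs$meth, bs$meth_watson + bs$meth_crick)
  expect_identical(bs$unmeth, bs$unmeth_watson + bs$unmeth_crick)
})

test_that("overlapping mates contribute one observation, higher quality wins", {
  # both mates of one fragment cover the CpG; mate 2 has higher quality and
  # shows T, mate 1 shows C
  aln <- rbindlist(list(
    makeAln("chrT", 2, "TTCGT", "OT", mate = 1, qual_w = strrep("5", 5),
            fragment_id = 1, frag_start = 2, frag_end = 8),
    makeAln("chrT", 2, "TTTGT", "OT", mate = 2, qual_w = strrep("I", 5),
            fragment_id = 1, frag_start = 2, frag_end = 8)))
  aln <- sortAln(aln)
  bs <- callCpGs(aln, cpgRef, cpgIdx, "bisulfite")
  expect_identical(bs$meth, 0L)
  expect_identical(bs$unmeth, 1L)
  # equal quality: mate 1 wins the tie
  aln2 <- rbindlist(list(
    makeAln("chrT", 2, "TTCGT", "OT", mate = 1, fragment_id = 1,
            frag_start = 2, frag_end = 8),
    makeAln("chrT", 2, "TTTGT", "OT", mate = 2, fragment_id = 1,
            frag_start = 2, frag_end = 8)))
  bs2 <- callCpGs(sortAln(aln2), cpgRef, cpgIdx, "bisulfite")
  expect_identical(bs2$meth, 1L)
  expect_identical(bs2$unmeth, 0L)
})

test_that("base and mapping quality filters drop sub-threshold observations", {
  lowQ <- makeAln("chrT", 2, "TTCGT", "OT", qual_w = "II#II",
                  fragment_id = 1)  # base at the CpG is Q2
  expect_identical(nrow(callCpGs(sortAln(lowQ), cpgRef, cpgIdx,
                                 "bisulfite")), 0L)
  lowM <- makeAln("chrT", 2, "TTCGT", "OT", mapq = 0L, fragment_id = 1)
  expect_identical(nrow(callCpGs(sortAln(lowM), cpgRef, cpgIdx,
                                 "bisulfite")), 0L)
})

test_that("chemistry duality swaps counts at every site on real-ish data", {
  cfg <- simConfig(genome_length = 8000L, n_fragments = 800L, seed = 23L)
  run <- simulateAndAlign(cfg)
  dd <- dedupAlignments(run$aln)
  bs <- callCpGs(dd$alignments, run$sim$ref, run$sim$idx, "bisulfite")
  tp <- callCpGs(dd$alignments, run$sim$ref, run$sim$idx, "taps")
  expect_identical(bs$pos, tp$pos)
  expect_identical(bs$meth, tp$unmeth)
  expect_identical(bs$unmeth, tp$meth)
  # count conservation: site totals equal the read-level observation count
  obs <- metharc:::cpgObservations(dd$alignments, run$sim$idx)
  setorder(obs, fragment_id, chrom, site, -qual, mate)
  nobs <- nrow(obs[!duplicated(obs[, .(fragment_id, chrom, site)])])
  expect_identical(sum(bs$meth + bs$unmeth), nobs)
})

test_that("conversion-rate estimation counts spike-in cytosines", {
  # lambda = CCC...: 98 T-observations and 2 C-observations at cytosines
  lam <- strrep("C", 10)
  ref <- ReferenceGenome(c(chr1 = "AATTCGTAA", lambda = lam))
  rows <- lapply(1:100, function(i)
    makeAln("lambda", 0, if (i <= 2) "CCCCCCCCCC" else "TTTTTTTTTT",
            "OT", fragment_id = i, is_spike_in = TRUE))
  aln <- sortAln(rbindlist(rows))
  cv <- conversionRate(aln, ref, "bisulfite")
  expect_true(cv$estimable)
  expect_equal(cv$rate, 0.98)
  expect_identical(cv$total_count, 1000L)
  # TAPS semantics: the same data read as retained-is-correct
  cvT <- conversionRate(aln, ref, "taps")
  expect_equal(cvT$rate, 0.02)
  # zero coverage -> flagged, not a number
  expect_warning(cv0 <- conversionRate(aln[0], ref, "bisulfite"),
                 "not estimable")
  expect_false(cv0$estimable)
  expect_true(is.na(cv0$rate))
})

test_that("M-bias attributes observations to original sequencing cycles", {
  # hand-computed two-read case on AATTCGTAA (CpG C at 4, G at 5):
  # read A: OT mate 1, forward at pos 2, covers the Watson C (pos 4) at
  #         read offset 2 -> cycle 3
  # read B: OB mate 1 (reversed on Watson) at pos 2, covers the Watson G
  #         (pos 5) at offset 3; cycle = (len-1-offset) + 1 = 2, shifted to
  #         4 by clip_head = 2
  ref <- cpgRef
  a <- makeAln("chrT", 2, "TTCGT", "OT", mate = 1, fragment_id = 1)
  b <- makeAln("chrT", 2, "TTCGA", "OB", mate = 1, fragment_id = 2,
               clip_head = 2L)
  mb <- mBias(sortAln(rbind(a, b)), ref, cpgIdx, "bisulfite")
  expect_identical(mb[mate == 1 & cycle == 3, meth], 1L)   # read A, C kept
  expect_identical(mb[mate == 1 & cycle == 4, meth], 1L)   # read B, G kept
  expect_identical(sum(mb$meth + mb$unmeth), 2L)
})

test_that("per-chromosome levels pool counts and exclude spike-ins", {
  calls <- data.table(
    chrom = c("chr1", "chr1", "lambda"), pos = c(4L, 10L, 3L),
    meth = c(10L, 0L, 5L), unmeth = c(20L, 10L, 0L),
    meth_watson = c(10L, 0L, 5L), unmeth_watson = c(20L, 10L, 0L),
    meth_crick = 0L, unmeth_crick = 0L,
    beta = c(1 / 3, 0, 1), is_spike_in = c(FALSE, FALSE, TRUE))
  ref <- ReferenceGenome(c(chr1 = "AATTCGTAA", chr2 = "ACGTACGT",
                           lambda = "CCGG"))
  lv <- perChromosomeLevels(calls, ref)
  expect_equal(unname(lv["chr1"]), 0.25)
  expect_false("lambda" %in% names(lv))
  expect_identical(attr(lv, "omitted"), "chr2")
  expect_equal(attr(lv, "overall"), 0.25)  # lambda excluded from overall
})
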