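test_that("read conversion follows the mate-specific rules", {
  expect_identical(convertReads("ACCGT", 1L, "three_letter"), "ATTGT")
  expect_identical(convertReads("AGGCT", 2L, "three_letter"), "AAACT")
  expect_identical(convertReads("ACGGT", 2L, "four_letter"), "ACAGT")
  expect_identical(convertReads("ACCGT", 1L, "four_letter"), "ACTGT")
  # leading G of mate 2 has unknown context and is preserved
  expect_identical(convertReads("GACG", 2L, "four_letter"), "GACA")
})

seRead <- function(seqs) {
  list(r1 = list(id = paste0("r", seq_along(seqs)), seq = seqs,
                 qual = strrep("I", nchar(seqs))),
       r2 = NULL, clip_head_r1 = 0L, clip_head_r2 = 0L,
       single_end = TRUE, stats = NULL)
}

test_that("planted exact reads align uniquely at the planted locus", {
  set.seed(13)
  ref <- ReferenceGenome(c(chr1 = randomSeq(5000)))
  pg <- buildPseudoGenome(ref, "three_letter")
  pseudo <- as.character(genomeSeqs(pg))
  read <- substr(pseudo[["chr1"]], 101, 150)  # alignment-space read
  pa <- builtinAlign(seRead(read), pg)
  expect_true(pa$mapped)
  expect_identical(pa$pseudo_chrom, "chr1")
  expect_identical(pa$pos1, 100L)
  expect_identical(pa$cigar1, "50M")
  expect_identical(pa$mapq, 42L)

  # read planted verbatim at two loci -> unmapped with multi flag
  dupseg <- randomSeq(60)
  g2 <- paste0(randomSeq(500), dupseg, randomSeq(500), dupseg,
               randomSeq(200))
  ref2 <- ReferenceGenome(c(chr1 = g2))
  pg2 <- buildPseudoGenome(ref2, "three_letter")
  r <- convertSequence(substr(dupseg, 5, 54), "three_letter")
  pa2 <- builtinAlign(seRead(r), pg2)
  expect_false(pa2$mapped)
  expect_true(pa2$multi)
  # with unique_only = FALSE the tie is broken deterministically
  pa3 <- builtinAlign(seRead(r), pg2, alignConfig(unique_only = FALSE,
                                                  seed = 5L))
  pa4 <- builtinAlign(seRead(r), pg2, alignConfig(unique_only = FALSE,
                                                  seed = 5L))
  expect_true(pa3$mapped)
  expect_identical(pa3$mapq, 0L)
  expect_identical(pa3$pos1, pa4$pos1)
})

test_that("crick-strand reads map to the #rev pseudo-chromosome and lift back", {
  set.seed(14)
  g <- randomSeq(3000)
  ref <- ReferenceGenome(c(chr1 = g))
  pg <- buildPseudoGenome(ref, "three_letter")
  # a fragment read from the crick strand, bisulfite-naive (no conversion):
  # its C->T converted form must match the crick pseudo-chromosome forward
  frag <- substr(g, 1001, 1080)
  crickRead <- convertSequence(revcompStr(frag), "three_letter")
  pa <- builtinAlign(seRead(crickRead), pg)
  expect_true(pa$mapped)
  expect_identical(pa$pseudo_chrom, "chr1#rev")
  lift <- liftPseudoAlignment(pg, pa$pseudo_chrom, pa$pos1, pa$cigar1)
  expect_identical(lift$chrom, "chr1")
  expect_identical(lift$pos, 1000L)
  expect_identical(lift$bs_strand, "OB")
})

test_that("coordinate lifting arithmetic matches the construction", {
  ref <- ReferenceGenome(c(c10 = "ACGTACGTAC"))
  pg <- buildPseudoGenome(ref, "three_letter")
  l <- liftPseudoAlignment(pg, "c10#rev", 2L, "4M")
  expect_identical(l$pos, 4L)          # 10 - 2 - 4
  expect_identical(l$bs_strand, "OB")
  expect_identical(l$cigar, "4M")
  l2 <- liftPseudoAlignment(pg, "c10", 7L, "3M")
  expect_identical(l2$pos, 7L)
  expect_identical(l2$bs_strand, "OT")
  # indel CIGAR reverses element-wise, reference span preserved
  l3 <- liftPseudoAlignment(pg, "c10#rev", 1L, "3M1D4M")
  expect_identical(l3$cigar, "4M1D3M")
  expect_identical(metharc:::cigarRefSpan(l3$cigar),
                   metharc:::cigarRefSpan("3M1D4M"))
  expect_identical(l3$pos, 10L - 1L - 8L)
  expect_error(liftPseudoAlignment(pg, "c10#rev", 8L, "4M"), "position < 0")
})

test_that("indel restoration agrees with a Needleman-Wunsch oracle", {
  set.seed(15)
  g <- randomSeq(400)
  ref <- ReferenceGenome(c(chr1 = g))
  pg <- buildPseudoGenome(ref, "four_letter")
  L <- 400L
  # build a crick-space read spanning crick [p, p+31) with one deletion:
  # 15M1D15M in pseudo space
  p <- 120L
  crick <- revcompStr(g)
  readCrick <- paste0(substr(crick, p + 1, p + 15),
                      substr(crick, p + 17, p + 31))
  lift <- liftPseudoAlignment(pg, "chr1#rev", p, "15M1D15M")
  expect_identical(lift$cigar, "15M1D15M")  # palindromic here
  expect_identical(lift$pos, L - p - 31L)
  # watson-oriented read bases = revcomp of the crick read
  readW <- revcompStr(readCrick)
  # independent reconstruction: walking the restored CIGAR over the Watson
  # genome from the restored position must reproduce the read exactly
  expected <- paste0(substr(g, lift$pos + 1L, lift$pos + 15L),
                     substr(g, lift$pos + 17L, lift$pos + 31L))
  expect_identical(readW, expected)
  # Needleman-Wunsch oracle recovers the same locus
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(readW), Biostrings::DNAString(g),
    type = "global-local", gapOpening = 4, gapExtension = 1)
  expect_identical(
    as.integer(Biostrings::start(Biostrings::subject(aln))) - 1L,
    lift$pos)
})

test_that("restored coordinates equal brute-force substring search", {
  # unconverted chemistry (conversion 0, error 0): every read is an exact
  # genomic substring, so exhaustive search is a complete oracle
  cfg <- simConfig(genome_length = 2000L, n_fragments = 200L,
                   conversion_rate = 0, inverse_failure = 0,
                   error_rate = 0, seed = 99L)
  run <- simulateAndAlign(cfg)
  g <- as.character(genomeSeqs(run$sim$ref))[["chr1"]]
  aln <- run$aln
  expect_gt(nrow(aln), 300L)
  for (i in seq_len(nrow(aln))) {
    hits <- bruteForceFind(aln$seq_w[i], g)  # seq_w is Watson-oriented
    expect_true(aln$pos[i] %in% hits)
  }
})

test_that("restoration round trip recovers the true origin of every read", {
  cfg <- simConfig(genome_length = 30000L, n_fragments = 1500L,
                   error_rate = 0, seed = 4L)
  run <- simulateAndAlign(cfg)
  ev <- evaluateAgainstTruth(run$aln, run$nReads)
  expect_gte(ev$mapping_efficiency, 0.99)
  expect_identical(ev$mapping_accuracy, 1)
  # conversion consistency: the converted read matches the converted
  # pseudo-chromosome at the reported locus within the mismatch budget
  pseqs <- as.character(genomeSeqs(run$pg))
  pa <- run$pa[mapped == TRUE][1:50]
  for (i in seq_len(nrow(pa))) {
    ridx <- match(pa$read_id[i], run$trimmed$r1$id)
    conv <- convertReads(run$trimmed$r1$seq[ridx], 1L, "three_letter")
    refseg <- substr(pseqs[[pa$pseudo_chrom[i]]], pa$pos1[i] + 1L,
                     pa$pos1[i] + nchar(conv))
    mm <- sum(strsplit(conv, "")[[1]] != strsplit(refseg, "")[[1]])
    expect_lte(mm, 4L)
  }
})

test_that("mapping metrics handle plain and degenerate inputs", {
  aln <- data.table::rbindlist(lapply(1:9, function(i)
    makeAln("chr1", 100 + i, "ACGT", "OT", fragment_id = i,
            read_id = sprintf("x%d:chr1:%d:%d:+", i, 100 + i, 104 + i))))
  ev <- evaluateAgainstTruth(aln, nReads = 10L)
  expect_equal(ev$mapping_efficiency, 0.9)
  expect_equal(ev$mapping_accuracy, 1)
  ev0 <- evaluateAgainstTruth(aln[0], nReads = 10L)
  expect_equal(ev0$mapping_efficiency, 0)
  expect_false(ev0$accuracy_defined)
  # reads without truth tags are excluded with a warning
  bad <- makeAln("chr1", 5, "ACGT", "OT", fragment_id = 99,
                 read_id = "anonymous")
  expect_warning(evaluateAgainstTruth(rbind(aln, bad), nReads = 10L),
                 "truth tags")
})

test_that("SE reads matching only in reverse orientation are rejected", {
  set.seed(16)
  g <- randomSeq(2000)
  ref <- ReferenceGenome(c(chr1 = g))
  pg <- buildPseudoGenome(ref, "three_letter")
  # the reverse complement OF A PSEUDO-CHROMOSOME SEGMENT is not a legal
  # converted read; the builtin aligner only searches forward, so it must
  # come back unmapped
  seg <- substr(as.character(genomeSeqs(pg))[["chr1"]], 501, 550)
  pa <- builtinAlign(seRead(revcompStr(seg)), pg)
  expect_false(pa$mapped)
  # and the SAM ingestion path drops flag-16 SE records
  sam <- c("@HD\tVN:1.6",
           paste("r1", 16L, "chr1", 101L, 42L, "50M", "*", 0L, 0L,
                 strrep("A", 50), strrep("I", 50), sep = "\t"),
           paste("r2", 0L, "chr1", 201L, 42L, "50M", "*", 0L, 0L,
                 strrep("A", 50), strrep("I", 50), sep = "\t"))
  parsed <- parseSamToPseudo(sam, single = TRUE)
  expect_identical(parsed[read_id == "r1", mapped], FALSE)
  expect_identical(parsed[read_id == "r2", mapped], TRUE)
  expect_identical(parsed[read_id == "r2", pos1], 200L)
})

test_that("external aligner absence yields an actionable error", {
  skip_if(nzchar(Sys.which("bowtie2")), "bowtie2 present")
  expect_error(externalAlign("r1.fq", NULL, tempdir(), "bowtie2"),
               "builtin")
})

test_that("emitted SAM passes format validation and names original chroms", {
  cfg <- simConfig(genome_length = 10000L, n_fragments = 300L, seed = 31L,
                   spike_in = TRUE)
  run <- simulateAndAlign(cfg)
  sam <- tempfile(fileext = ".sam")
  writeSamFile(run$aln, run$sim$ref, sam)
  lines <- readLines(sam)
  expect_identical(validateSamLines(lines, chromLengths(run$sim$ref)), TRUE)
  sq <- grep("^@SQ", lines, value = TRUE)
  expect_identical(sub(".*SN:([^\t]+).*", "\\1", sq),
                   chromNames(run$sim$ref))
  expect_false(any(grepl("#rev\t", lines)))  # no pseudo names in records
  recs <- grep("^@", lines, invert = TRUE, value = TRUE)
  expect_true(all(grepl("XS:Z:(OT|OB)", recs)))
  flags <- as.integer(vapply(strsplit(recs, "\t"), `[[`, "", 2))
  expect_true(all(flags %in% c(83L, 99L, 147L, 163L)))
})
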