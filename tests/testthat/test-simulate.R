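test_that("genome simulation is reproducible and covers its CpG index", {
  cfg <- simConfig(genome_length = 1000L, seed = 7L)
  a <- simulateGenome(cfg)
  b <- simulateGenome(cfg)
  expect_identical(as.character(genomeSeqs(a$ref)),
                   as.character(genomeSeqs(b$ref)))
  expect_identical(a$truth, b$truth)
  # truth table covers exactly the CpG index
  expect_identical(a$truth$pos[a$truth$chrom == "chr1"],
                   metharc:::cpgPositions0(a$idx, "chr1"))

  cfgBig <- simConfig(genome_length = 100000L, seed = 8L)
  g <- as.character(genomeSeqs(simulateGenome(cfgBig)$ref))[["chr1"]]
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / nchar(g)
  expect_lt(abs(gc - 0.5), 4 * sqrt(0.25 / 100000))
})

test_that("spike-in chromosome is present, unmethylated and 5 kb", {
  cfg <- simConfig(genome_length = 2000L, spike_in = TRUE, seed = 2L)
  sim <- simulateGenome(cfg)
  expect_identical(chromNames(sim$ref), c("chr1", "lambda"))
  expect_identical(unname(chromLengths(sim$ref)["lambda"]), 5000L)
  expect_identical(spikeIns(sim$ref), "lambda")
  expect_true(all(sim$truth[chrom == "lambda", beta] == 0))
})

test_that("read simulation is byte-deterministic under a fixed seed", {
  cfg <- simConfig(genome_length = 3000L, n_fragments = 100L, seed = 5L)
  sim <- simulateGenome(cfg)
  r1 <- simulateReads(sim$ref, sim$truth, cfg)
  r2 <- simulateReads(sim$ref, sim$truth, cfg)
  expect_identical(r1, r2)
  p1 <- tempfile(fileext = ".fq.gz"); p2 <- tempfile(fileext = ".fq.gz")
  writeFastq(r1$r1, p1); writeFastq(r2$r1, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("chemistry limit cases behave as the rules force", {
  # full conversion, all-unmethylated, bisulfite, no errors: no C survives
  # at genomic C positions of + strand fragments
  cfg <- simConfig(genome_length = 3000L, n_fragments = 60L, seed = 9L,
                   conversion_rate = 1, inverse_failure = 0,
                   error_rate = 0, truth_betas = 0)
  sim <- simulateGenome(cfg)
  reads <- simulateReads(sim$ref, sim$truth, cfg)
  g <- as.character(genomeSeqs(sim$ref))[["chr1"]]
  for (i in seq_len(20)) {
    tr <- strsplit(reads$r1$id[i], ":")[[1]]
    if (tr[5] != "+") next
    st <- as.integer(tr[3]); en <- as.integer(tr[4])
    frag <- substr(g, st + 1, min(en, st + cfg$read_len))
    cpos <- which(strsplit(frag, "")[[1]] == "C")
    got <- strsplit(substr(reads$r1$seq[i], 1, nchar(frag)), "")[[1]]
    expect_false(any(got[cpos] == "C"))
    expect_true(all(got[cpos] == "T"))
  }

  # zero conversion: reads are verbatim genome fragments
  cfg0 <- simConfig(genome_length = 3000L, n_fragments = 60L, seed = 9L,
                    conversion_rate = 0, inverse_failure = 0,
                    error_rate = 0, truth_betas = 0)
  reads0 <- simulateReads(sim$ref, sim$truth, cfg0)
  for (i in seq_len(20)) {
    tr <- strsplit(reads0$r1$id[i], ":")[[1]]
    st <- as.integer(tr[3]); en <- as.integer(tr[4])
    frag <- substr(g, st + 1, en)
    tmpl <- if (tr[5] == "+") frag else revcompStr(frag)
    expect_identical(reads0$r1$seq[i],
                     substr(tmpl, 1, min(nchar(tmpl), cfg$read_len)))
  }
})

test_that("observed methylation matches the chemistry algebra", {
  # single-CpG genome, truth beta 0.3, high depth; the probability that a
  # read shows the methylated state is b*(1-f) + (1-b)*(1-c) for bisulfite
  b <- 0.3; cr <- 0.95; fl <- 0.02
  g <- paste0(strrep("AT", 40), "ACGT", strrep("TA", 40))
  depth <- 2000L
  cfg <- simConfig(genome_length = nchar(g), n_fragments = depth,
                   read_len = 36L, frag_mean = 80, frag_sd = 10,
                   paired = FALSE, conversion_rate = cr,
                   inverse_failure = fl, error_rate = 0,
                   truth_betas = b, seed = 12L)
  ref <- ReferenceGenome(c(chr1 = g), spikeIns = character(0))
  idx <- buildCpGIndex(ref)
  pos <- metharc:::cpgPositions0(idx, "chr1")
  expect_identical(length(pos), 1L)
  truth <- data.table::data.table(chrom = "chr1", pos = pos, beta = b)
  set.seed(cfg$seed)
  reads <- simulateReads(ref, truth, cfg)
  # count read-level states directly at the C (for + fragments covering it)
  nm <- 0L; nt <- 0L
  for (i in seq_len(depth)) {
    tr <- strsplit(reads$r1$id[i], ":")[[1]]
    st <- as.integer(tr[3]); en <- as.integer(tr[4])
    if (tr[5] != "+" || st > pos || st + cfg$read_len <= pos) next
    base <- substr(reads$r1$seq[i], pos - st + 1L, pos - st + 1L)
    if (base == "C") nm <- nm + 1L
    if (base == "T") nt <- nt + 1L
  }
  pexp <- b * (1 - fl) + (1 - b) * (1 - cr)
  n <- nm + nt
  expect_gt(n, 200L)
  expect_lt(abs(nm / n - pexp), 4 * sqrt(pexp * (1 - pexp) / n))
})

test_that("CT-rich window finder agrees with a naive recount oracle", {
  ref1 <- ReferenceGenome(c(x = strrep("CT", 300)), spikeIns = character(0))
  w <- findCtRichWindows(ref1, 0.7, 200L)
  expect_identical(nrow(w), 1L)
  expect_identical(w$start, 0L)
  expect_gte(w$end, 500L)

  ref2 <- ReferenceGenome(c(x = strrep("GA", 300)), spikeIns = character(0))
  expect_identical(nrow(findCtRichWindows(ref2, 0.7, 200L)), 0L)

  set.seed(33)
  s <- paste0(randomSeq(4000), strrep("CTT", 500), randomSeq(4000))
  ref3 <- ReferenceGenome(c(x = s), spikeIns = character(0))
  got <- findCtRichWindows(ref3, 0.7, 200L)
  # naive oracle: same stride, per-window letter recount, manual merge
  chars <- strsplit(s, "")[[1]]
  starts <- seq(1L, nchar(s) - 200L + 1L, by = 100L)
  ok <- vapply(starts, function(st)
    mean(chars[st:(st + 199L)] %in% c("C", "T")) >= 0.7, logical(1))
  ir <- IRanges::reduce(IRanges::IRanges(start = starts[ok], width = 200L))
  expect_identical(got$start, IRanges::start(ir) - 1L)
  expect_identical(got$end, IRanges::end(ir))
})

test_that("ct_rich sampling places fragments inside CT-rich windows", {
  set.seed(44)
  s <- paste0(randomSeq(3000), strrep("CTT", 400), randomSeq(3000))
  cfg <- simConfig(genome_length = nchar(s), n_fragments = 50L,
                   ct_rich = TRUE, seed = 10L, frag_mean = 120,
                   frag_sd = 10)
  ref <- ReferenceGenome(c(chr1 = s), spikeIns = character(0))
  idx <- buildCpGIndex(ref)
  truth <- data.table::data.table(
    chrom = "chr1", pos = metharc:::cpgPositions0(idx, "chr1"), beta = 0.5)
  reads <- simulateReads(ref, truth, cfg)
  wW <- findCtRichWindows(ref, 0.7, 200L, "watson")
  wC <- findCtRichWindows(ref, 0.7, 200L, "crick")
  for (i in seq_len(50)) {
    tr <- strsplit(reads$r1$id[i], ":")[[1]]
    st <- as.integer(tr[3])
    w <- if (tr[5] == "+") wW else wC
    expect_true(any(st >= w$start & st <= w$end))
  }
})
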