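# Shared fixtures and independent oracles used across the suite.

randomSeq <- function(n, letters = c("A", "C", "G", "T")) {
  paste0(sample(letters, n, replace = TRUE), collapse = "")
}

writeTempFasta <- function(seqs) {
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(Map(function(nm, s) c(paste0(">", nm), s),
                        names(seqs), seqs)), fa)
  fa
}

revcompStr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# naive CpG scan oracle: 0-based positions of C in "CG"
naiveCpGScan <- function(s) {
  m <- gregexpr("CG", s, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# brute-force substring search oracle: all 0-based start positions of
# pattern (exact) in subject
bruteForceFind <- function(pattern, subject) {
  hits <- integer(0)
  n <- nchar(subject) - nchar(pattern) + 1L
  if (n < 1L) return(hits)
  for (i in seq_len(n))
    if (substr(subject, i, i + nchar(pattern) - 1L) == pattern)
      hits <- c(hits, i - 1L)
  hits
}

# hand-rolled construction of a restored-alignment row, for fixture-driven
# methylation-calling tests
makeAln <- function(chrom, pos, seq_w, bs_strand, mate = 1L,
                    qual_w = strrep("I", nchar(seq_w)),
                    cigar = paste0(nchar(seq_w), "M"),
                    reversed_w = (bs_strand == "OT") == (mate == 2L),
                    clip_head = 0L, fragment_id, frag_start = pos,
                    frag_end = pos + nchar(seq_w),
                    fragment_len = frag_end - frag_start, mapq = 42L,
                    is_spike_in = FALSE,
                    read_id = paste0("read", fragment_id)) {
  data.table::data.table(
    read_id = read_id, mate = as.integer(mate), chrom = chrom,
    pos = as.integer(pos), cigar = cigar, mapq = as.integer(mapq),
    bs_strand = bs_strand, seq_w = seq_w, qual_w = qual_w,
    reversed_w = reversed_w, clip_head = as.integer(clip_head),
    fragment_id = as.integer(fragment_id),
    frag_start = as.integer(frag_start), frag_end = as.integer(frag_end),
    fragment_len = as.integer(fragment_len), pseudo_chrom = chrom,
    is_spike_in = is_spike_in)
}

sortAln <- function(aln) {
  data.table::setorder(aln, chrom, frag_start, fragment_id, mate)
  aln
}

# small simulated dataset run through trim+align+restore in one call
simulateAndAlign <- function(cfg, mode = "three_letter",
                             trimCfg = trimConfig(),
                             alignCfg = alignConfig()) {
  sim <- simulateGenome(cfg)
  reads <- simulateReads(sim$ref, sim$truth, cfg)
  tr <- trimReadPairs(reads$r1, reads$r2, trimCfg)
  pg <- buildPseudoGenome(sim$ref, mode)
  pa <- builtinAlign(tr, pg, alignCfg)
  aln <- restoreAlignments(pa, tr, pg, sim$ref)
  list(sim = sim, reads = reads, trimmed = tr, pg = pg, pa = pa, aln = aln,
       nReads = length(reads$r1$seq) * (if (cfg$paired) 2L else 1L))
}

# minimal SAM record validation (field count, ranges, seq/cigar agreement)
validateSamLines <- function(lines, chromLens) {
  recs <- lines[!startsWith(lines, "@")]
  for (r in recs) {
    f <- strsplit(r, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) return(sprintf("too few fields: %s", r))
    flag <- as.integer(f[2]); pos <- as.integer(f[4])
    if (is.na(flag) || flag < 0) return("bad flag")
    if (!f[3] %in% names(chromLens)) return("unknown chrom")
    span <- metharc:::cigarRefSpan(f[6])
    if (pos < 1 || pos - 1 + span > chromLens[[f[3]]])
      return("alignment out of chromosome bounds")
    if (nchar(f[10]) != metharc:::cigarReadSpan(f[6]))
      return("SEQ length disagrees with CIGAR")
    if (nchar(f[10]) != nchar(f[11])) return("SEQ/QUAL length mismatch")
  }
  TRUE
}
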