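#' Convert read bases for alignment
#'
#' Read-side counterpart of \code{\link{convertSequence}}, following the
#' directional-library convention: mate 1 reads the converted strand
#' (C-to-T rule) and mate 2 its complement (G-to-A rule).  In four-letter
#' mode conversion is restricted to CpG context: mate 1 converts a C only
#' when followed by G, mate 2 converts a G only when preceded by C; a
#' terminal C (mate 1) or leading G (mate 2) has unknown context and is
#' preserved.
#'
#' @param seqs Character vector of read sequences.
#' @param mate 1 or 2.
#' @param mode \code{"three_letter"} or \code{"four_letter"}.
#' @return Converted sequences (same lengths).
#' @export
convertReads <- function(seqs, mate, mode = c("three_letter", "four_letter")) {
  mode <- match.arg(mode)
  stopifnot(mate %in% c(1L, 2L))
  if (mode == "three_letter") {
    if (mate == 1L) gsub("C", "T", seqs, fixed = TRUE)
    else gsub("G", "A", seqs, fixed = TRUE)
  } else {
    if (mate == 1L) gsub("CG", "TG", seqs, fixed = TRUE)
    else gsub("CG", "CA", seqs, fixed = TRUE)
  }
}

#' Built-in aligner configuration
#'
#' @param k Seed k-mer length.
#' @param stride Seed stride from the read start.
#' @param max_mismatch_per100 Mismatch allowance per 100 bp of read length
#'   (scaled by length, floored).
#' @param max_insert Maximum paired-end fragment length.
#' @param unique_only If TRUE (default) reads whose best score is tied
#'   across loci are reported unmapped (multi-hit); if FALSE one tied locus
#'   is picked deterministically from \code{seed}.
#' @param seed Integer seed for tie-breaking when \code{unique_only=FALSE}.
#' @param max_hits_per_kmer Seeds occurring more often than this in the
#'   pseudo-genome are skipped as repetitive.
#' @return An alignment-configuration list.
#' @export
alignConfig <- function(k = 16L, stride = 4L, max_mismatch_per100 = 4,
                        max_insert = 1000L, unique_only = TRUE, seed = 1L,
                        max_hits_per_kmer = 256L) {
  list(k = as.integer(k), stride = as.integer(stride),
       max_mismatch_per100 = max_mismatch_per100,
       max_insert = as.integer(max_insert), unique_only = unique_only,
       seed = as.integer(seed),
       max_hits_per_kmer = as.integer(max_hits_per_kmer))
}

#' Align converted reads against the pseudo-genome (built-in aligner)
#'
#' Exact-seed (k-mer) and ungapped-extension alignment against the combined
#' Watson+Crick pseudo-genome.  Because both converted strands are present,
#' single-end reads are only accepted in forward orientation (a converted
#' read that matches only as a reverse complement is chemically
#' inconsistent); paired-end mate 2 is reverse-complemented internally and
#' required to pair FR on the same pseudo-chromosome within
#' \code{max_insert}.  MAPQ is 42 for unique best hits and 0 for
#' tie-broken ones.
#'
#' @param trimmed Output of \code{\link{trimReadPairs}} (or a compatible
#'   list with \code{r1}, optionally \code{r2}, and \code{single_end}).
#' @param pg A \linkS4class{PseudoGenome}.
#' @param cfg An \code{\link{alignConfig}}.
#' @param threads Number of read chunks processed via
#'   \code{parallel::mclapply}; results are merged in input order so output
#'   is independent of this value.
#' @return A \code{data.table} with one row per read (pair): \code{read_id},
#'   \code{mapped}, \code{multi}, \code{pseudo_chrom}, \code{pos1},
#'   \code{pos2} (0-based, NA for SE), \code{len1}, \code{len2},
#'   \code{cigar1}, \code{cigar2}, \code{mm}, \code{mapq}.
#' @export
builtinAlign <- function(trimmed, pg, cfg = alignConfig(), threads = 1L) {
  stopifnot(is(pg, "PseudoGenome"))
  mode <- conversionMode(pg)
  single <- isTRUE(trimmed$single_end)
  n <- length(trimmed$r1$seq)
  conv1 <- convertReads(trimmed$r1$seq, 1L, mode)
  conv2rc <- if (!single)
    revcompChar(convertReads(trimmed$r2$seq, 2L, mode))
  pseqs <- as.character(genomeSeqs(pg))

  alignChunk <- function(ix) {
    res <- .cppAlign(conv1[ix], if (single) NULL else conv2rc[ix],
                     pseqs, cfg$k, cfg$stride, cfg$max_mismatch_per100,
                     cfg$max_insert, cfg$unique_only, cfg$seed,
                     as.integer(ix[1]) - 1L, cfg$max_hits_per_kmer)
    as.data.table(res)
  }
  chunks <- chunkIndices(n, threads)
  parts <- if (threads > 1L && length(chunks) > 1L)
    parallel::mclapply(chunks, alignChunk, mc.cores = threads)
  else lapply(chunks, alignChunk)
  res <- rbindlist(parts)

  len1 <- nchar(trimmed$r1$seq)
  len2 <- if (single) rep(NA_integer_, n) else nchar(trimmed$r2$seq)
  pa <- data.table(
    read_id = trimmed$r1$id,
    mapped = res$chrom > 0L,
    multi = res$multi,
    pseudo_chrom = fifelse(res$chrom > 0L, chromNames(pg)[pmax(res$chrom, 1L)],
                           NA_character_),
    pos1 = res$pos1, pos2 = res$pos2,
    len1 = len1, len2 = len2,
    cigar1 = paste0(len1, "M"),
    cigar2 = if (single) NA_character_ else paste0(len2, "M"),
    mm = res$mm,
    mapq = fifelse(res$chrom > 0L, fifelse(res$multi, 0L, 42L), NA_integer_))
  pa
}

chunkIndices <- function(n, threads) {
  if (n == 0L) return(list(integer(0)))
  threads <- max(1L, as.integer(threads))
  size <- ceiling(n / threads)
  split(seq_len(n), ceiling(seq_len(n) / size))
}

#' Align via an external aligner binary (bowtie2 / hisat2)
#'
#' Builds (once) the external aligner's own index over the pseudo-genome
#' FASTA, runs the aligner in end-to-end mode without unpaired/discordant
#' rescue, and parses the SAM output into the same pseudo-alignment table
#' as \code{\link{builtinAlign}}.  Single-end records aligned in reverse
#' orientation are discarded as chemically inconsistent.
#'
#' @param fastq1,fastq2 Trimmed FASTQ path(s); \code{fastq2 = NULL} for SE.
#' @param indexDir A directory written by \code{\link{writeGenomeIndex}}.
#' @param aligner \code{"bowtie2"} or \code{"hisat2"}.
#' @param threads Threads passed to the external binary.
#' @return A pseudo-alignment \code{data.table} (see
#'   \code{\link{builtinAlign}}).
#' @export
externalAlign <- function(fastq1, fastq2 = NULL, indexDir,
                          aligner = c("bowtie2", "hisat2"), threads = 1L) {
  aligner <- match.arg(aligner)
  bin <- Sys.which(aligner)
  if (!nzchar(bin))
    stop(aligner, " was not found on PATH; install it or use ",
         "aligner = \"builtin\" (builtinAlign) instead", call. = FALSE)
  fa <- file.path(indexDir, "pseudo_genome.fa")
  idxBase <- file.path(indexDir, paste0(aligner, "_index"))
  builder <- paste0(aligner, "-build")
  if (!file.exists(paste0(idxBase, ".1.bt2")) &&
      !file.exists(paste0(idxBase, ".1.ht2"))) {
    rc <- system2(Sys.which(builder), c(shQuote(fa), shQuote(idxBase)),
                  stdout = FALSE, stderr = FALSE)
    if (rc != 0) stop(builder, " failed with exit code ", rc)
  }
  sam <- tempfile(fileext = ".sam")
  args <- c("--end-to-end", "--no-mixed", "--no-discordant",
            "-p", threads, "-x", shQuote(idxBase),
            if (is.null(fastq2)) c("-U", shQuote(fastq1))
            else c("-1", shQuote(fastq1), "-2", shQuote(fastq2)),
            "-S", shQuote(sam))
  err <- tempfile()
  rc <- system2(bin, args, stdout = FALSE, stderr = err)
  if (rc != 0)
    stop(aligner, " failed (exit ", rc, "): ",
         paste(utils::tail(readLines(err, warn = FALSE), 5), collapse = " "))
  parseSamToPseudo(readLines(sam), single = is.null(fastq2))
}

#' Parse SAM alignment lines into a pseudo-alignment table
#'
#' Understands the subset of SAM needed to ingest external-aligner output
#' over the pseudo-genome: flag decoding (reverse, mate, unmapped), 1-based
#' to 0-based position shift, CIGAR passthrough.  Single-end reverse-strand
#' records are dropped (see \code{\link{externalAlign}}).
#'
#' @param lines Character vector of SAM lines (header lines ignored).
#' @param single Single-end data?
#' @return A pseudo-alignment \code{data.table}.
#' @export
parseSamToPseudo <- function(lines, single = FALSE) {
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.table(read_id = character(0), mapped = logical(0),
                      multi = logical(0), pseudo_chrom = character(0),
                      pos1 = integer(0), pos2 = integer(0),
                      len1 = integer(0), len2 = integer(0),
                      cigar1 = character(0), cigar2 = character(0),
                      mm = integer(0), mapq = integer(0)))
  f <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:10)
  rec <- data.table(read_id = f[[1]], flag = as.integer(f[[2]]),
                    chrom = f[[3]], pos = as.integer(f[[4]]) - 1L,
                    mapq = as.integer(f[[5]]), cigar = f[[6]],
                    seq = f[[10]])
  rec[, mapped := bitwAnd(flag, 4L) == 0L]
  rec[, reverse := bitwAnd(flag, 16L) == 16L]
  rec[, mate := fifelse(bitwAnd(flag, 128L) == 128L, 2L, 1L)]
  rec <- rec[bitwAnd(flag, 256L) == 0L & bitwAnd(flag, 2048L) == 0L]
  if (single) {
    rec <- rec[mate == 1L]
    rec[reverse & mapped, mapped := FALSE]  # chemically inconsistent
    out <- rec[, .(read_id, mapped, multi = FALSE,
                   pseudo_chrom = fifelse(mapped, chrom, NA_character_),
                   pos1 = fifelse(mapped, pos, NA_integer_),
                   pos2 = NA_integer_, len1 = nchar(seq),
                   len2 = NA_integer_,
                   cigar1 = fifelse(mapped, cigar, NA_character_),
                   cigar2 = NA_character_, mm = NA_integer_, mapq)]
    return(out)
  }
  m1 <- rec[mate == 1L]
  m2 <- rec[mate == 2L]
  setkey(m1, read_id); setkey(m2, read_id)
  j <- m1[m2, nomatch = 0L]
  j[, ok := mapped & i.mapped & chrom == i.chrom]
  j[, .(read_id, mapped = ok, multi = FALSE,
        pseudo_chrom = fifelse(ok, chrom, NA_character_),
        pos1 = fifelse(ok, pmin(pos, i.pos), NA_integer_),
        pos2 = fifelse(ok, pmax(pos, i.pos), NA_integer_),
        len1 = nchar(seq), len2 = nchar(i.seq),
        cigar1 = fifelse(ok, cigar, NA_character_),
        cigar2 = fifelse(ok, i.cigar, NA_character_),
        mm = NA_integer_, mapq = pmin(mapq, i.mapq))]
}

#' Lift a pseudo-genome alignment to Watson coordinates
#'
#' The restoration arithmetic forced by the pseudo-genome construction: a
#' hit on a Watson-origin pseudo-chromosome keeps its position and CIGAR
#' (bisulfite strand OT); a hit at position p with reference span s on a
#' Crick-origin pseudo-chromosome of original length L lifts to Watson
#' position \code{L - p - s} with the CIGAR reversed element-wise
#' (bisulfite strand OB).
#'
#' @param pg A \linkS4class{PseudoGenome}.
#' @param pseudo_chrom Pseudo-chromosome names.
#' @param pos 0-based leftmost positions on the pseudo-chromosome.
#' @param cigar CIGAR strings.
#' @return A \code{data.table} with \code{chrom}, \code{pos} (0-based
#'   Watson), \code{cigar} (Watson orientation), \code{bs_strand}
#'   ("OT"/"OB").
#' @export
liftPseudoAlignment <- function(pg, pseudo_chrom, pos, cigar) {
  o <- originTable(pg)
  i <- match(pseudo_chrom, o$pseudo_name)
  if (anyNA(i)) stop("unknown pseudo-chromosome: ",
                     paste(unique(pseudo_chrom[is.na(i)]), collapse = ", "))
  span <- cigarRefSpan(cigar)
  crick <- o$strand[i] == "crick"
  outpos <- ifelse(crick, o$length[i] - pos - span, pos)
  if (any(outpos < 0))
    stop("restored position < 0: corrupt index or alignment")
  if (any(outpos + span > o$length[i]))
    stop("restored alignment exceeds chromosome length")
  data.table(chrom = o$orig_name[i], pos = as.integer(outpos),
             cigar = ifelse(crick, reverseCigar(cigar), cigar),
             bs_strand = ifelse(crick, "OB", "OT"))
}

#' Restore pseudo-alignments to original coordinates, strands and bases
#'
#' Lifts every mapped read (pair) from pseudo-genome space back to Watson
#' coordinates of the original genome, infers the bisulfite strand (OT =
#' fragment from Watson, OB = from Crick), and reorients the original
#' (unconverted) bases and qualities to Watson so that downstream
#' methylation calling reads them directly.
#'
#' @param pa Pseudo-alignment table from \code{\link{builtinAlign}} /
#'   \code{\link{externalAlign}}.
#' @param trimmed The trimmed reads the table was produced from (original
#'   bases; see \code{\link{trimReadPairs}}).
#' @param pg The \linkS4class{PseudoGenome} aligned against.
#' @param ref The original \linkS4class{ReferenceGenome}.
#' @return A \code{data.table} with one row per aligned mate:
#'   \code{read_id}, \code{mate}, \code{chrom}, \code{pos} (0-based
#'   Watson), \code{cigar}, \code{mapq}, \code{bs_strand}, \code{seq_w} /
#'   \code{qual_w} (Watson-oriented), \code{reversed_w} (TRUE when Watson
#'   orientation reverses sequencing order), \code{clip_head} (cycles
#'   clipped at the read 5', for cycle attribution), \code{fragment_id},
#'   \code{frag_start}/\code{frag_end} (0-based half-open Watson fragment),
#'   \code{fragment_len} (0 for SE), \code{pseudo_chrom},
#'   \code{is_spike_in}.
#' @export
restoreAlignments <- function(pa, trimmed, pg, ref) {
  single <- isTRUE(trimmed$single_end)
  keep <- which(pa$mapped)
  emptyCols <- function()
    data.table(read_id = character(0), mate = integer(0),
               chrom = character(0), pos = integer(0), cigar = character(0),
               mapq = integer(0), bs_strand = character(0),
               seq_w = character(0), qual_w = character(0),
               reversed_w = logical(0), clip_head = integer(0),
               fragment_id = integer(0), frag_start = integer(0),
               frag_end = integer(0), fragment_len = integer(0),
               pseudo_chrom = character(0), is_spike_in = logical(0))
  if (!length(keep)) return(emptyCols())
  o <- originTable(pg)
  oi <- match(pa$pseudo_chrom[keep], o$pseudo_name)
  L <- o$length[oi]
  crick <- o$strand[oi] == "crick"
  chrom <- o$orig_name[oi]
  spike <- chrom %in% ref@spikeIns

  l1 <- liftPseudoAlignment(pg, pa$pseudo_chrom[keep], pa$pos1[keep],
                            pa$cigar1[keep])
  seq1 <- trimmed$r1$seq[keep]
  qual1 <- trimmed$r1$qual[keep]
  rev1 <- crick  # OT mate1 forward, OB mate1 reversed on Watson
  m1 <- data.table(
    read_id = pa$read_id[keep], mate = 1L,
    chrom = chrom, pos = l1$pos, cigar = l1$cigar, mapq = pa$mapq[keep],
    bs_strand = l1$bs_strand,
    seq_w = ifelse(rev1, revcompChar(seq1), seq1),
    qual_w = ifelse(rev1, reverseString(qual1), qual1),
    reversed_w = rev1,
    clip_head = trimmed$clip_head_r1 %||% 0L,
    fragment_id = keep,
    pseudo_chrom = pa$pseudo_chrom[keep], is_spike_in = spike)

  if (single) {
    span1 <- cigarRefSpan(l1$cigar)
    m1[, `:=`(frag_start = pos, frag_end = pos + span1, fragment_len = 0L)]
    setorder(m1, chrom, pos, fragment_id)
    return(m1[])
  }

  l2 <- liftPseudoAlignment(pg, pa$pseudo_chrom[keep], pa$pos2[keep],
                            pa$cigar2[keep])
  seq2 <- trimmed$r2$seq[keep]
  qual2 <- trimmed$r2$qual[keep]
  rev2 <- !crick  # OT mate2 reversed on Watson, OB mate2 forward
  m2 <- data.table(
    read_id = pa$read_id[keep], mate = 2L,
    chrom = chrom, pos = l2$pos, cigar = l2$cigar, mapq = pa$mapq[keep],
    bs_strand = l2$bs_strand,
    seq_w = ifelse(rev2, revcompChar(seq2), seq2),
    qual_w = ifelse(rev2, reverseString(qual2), qual2),
    reversed_w = rev2,
    clip_head = trimmed$clip_head_r2 %||% 0L,
    fragment_id = keep,
    pseudo_chrom = pa$pseudo_chrom[keep], is_spike_in = spike)

  # fragment on the pseudo-chromosome is [pos1, pos2 + span2); lift to Watson
  span2p <- cigarRefSpan(pa$cigar2[keep])
  pstart <- pa$pos1[keep]
  pend <- pa$pos2[keep] + span2p
  fstart <- as.integer(ifelse(crick, L - pend, pstart))
  fend <- as.integer(ifelse(crick, L - pstart, pend))
  flen <- fend - fstart
  for (m in list(m1, m2))
    m[, `:=`(frag_start = fstart, frag_end = fend, fragment_len = flen)]
  out <- rbindlist(list(m1, m2))
  setorder(out, chrom, pos, fragment_id, mate)
  out[]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mapping efficiency and accuracy against simulator truth
#'
#' Read IDs produced by \code{\link{simulateReads}} carry their true origin
#' as \code{id:chrom:start:end:strand}.  Mapping efficiency is the fraction
#' of raw reads that are mapped; accuracy is the fraction of reported
#' alignments whose restored (chrom, pos, strand) matches the truth within
#' \code{tol} bp.
#'
#' @param aln Restored alignment table (\code{\link{restoreAlignments}}).
#' @param nReads Total raw reads that entered alignment (counting both
#'   mates of a pair separately).
#' @param tol Position tolerance in bp (default 0, exact).
#' @return A list: \code{mapping_efficiency}, \code{mapping_accuracy},
#'   \code{n_reads}, \code{n_mapped}, \code{n_correct},
#'   \code{accuracy_defined}.
#' @export
evaluateAgainstTruth <- function(aln, nReads, tol = 0L) {
  truth <- data.table::tstrsplit(aln$read_id, ":", fixed = TRUE)
  if (length(truth) < 5) {
    bad <- rep(TRUE, nrow(aln))
  } else {
    tchrom <- truth[[length(truth) - 3L]]
    tstart <- suppressWarnings(as.integer(truth[[length(truth) - 2L]]))
    tend <- suppressWarnings(as.integer(truth[[length(truth) - 1L]]))
    tstrand <- truth[[length(truth)]]
    bad <- is.na(tstart) | is.na(tend) | !tstrand %in% c("+", "-")
  }
  if (any(bad)) {
    warning(sum(bad), " alignment(s) lacking truth tags were excluded")
    aln <- aln[!bad]
    tchrom <- tchrom[!bad]; tstart <- tstart[!bad]
    tend <- tend[!bad]; tstrand <- tstrand[!bad]
  }
  nMapped <- nrow(aln)
  if (nMapped == 0L)
    return(list(mapping_efficiency = 0, mapping_accuracy = 0,
                n_reads = nReads, n_mapped = 0L, n_correct = 0L,
                accuracy_defined = FALSE))
  span <- cigarRefSpan(aln$cigar)
  expStrand <- ifelse(tstrand == "+", "OT", "OB")
  # leftmost Watson position expected for this mate, given its aligned span
  expPos <- ifelse((tstrand == "+") == (aln$mate == 1L),
                   tstart, tend - span)
  correct <- aln$chrom == tchrom & aln$bs_strand == expStrand &
    abs(aln$pos - expPos) <= tol
  nCorrect <- sum(correct)
  list(mapping_efficiency = nMapped / nReads,
       mapping_accuracy = nCorrect / nMapped,
       n_reads = nReads, n_mapped = nMapped, n_correct = nCorrect,
       accuracy_defined = TRUE)
}

# ---- SAM emission ----------------------------------------------------------

samFlags <- function(aln, single) {
  if (single) return(ifelse(aln$reversed_w, 16L, 0L))
  flag <- 1L + 2L + ifelse(aln$mate == 1L, 64L, 128L) +
    ifelse(aln$reversed_w, 16L, 0L) + ifelse(aln$reversed_w, 0L, 32L)
  flag
}

#' Write restored alignments as SAM (and optionally BAM)
#'
#' The header names original chromosomes only; each record carries the
#' bisulfite strand as \code{XS:Z} and the pseudo-chromosome of origin as
#' \code{XO:Z}.  Records are coordinate-sorted.  When the Rsamtools package
#' is available and \code{bam = TRUE} a sorted BAM with index is produced
#' alongside.
#'
#' @param aln Restored alignment table.
#' @param ref The \linkS4class{ReferenceGenome}.
#' @param path Output SAM path.
#' @param bam Also convert to BAM (requires Rsamtools).
#' @param programLine Extra \code{@PG} header line (deterministic content is
#'   the caller's responsibility).
#' @return Invisibly, the SAM path.
#' @export
writeSamFile <- function(aln, ref, path, bam = FALSE,
                         programLine = "@PG\tID:metharc\tPN:metharc") {
  single <- all(aln$fragment_len == 0L)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", chromNames(ref), "\tLN:",
                  unname(chromLengths(ref))),
           programLine)
  aln <- copy(aln)
  aln[, .ord := match(chrom, chromNames(ref))]
  setorder(aln, .ord, pos, fragment_id, mate)
  aln[, .ord := NULL]
  if (nrow(aln)) {
    flag <- samFlags(aln, single)
    if (single) {
      rnext <- "*"; pnext <- 0L; tlen <- 0L
    } else {
      other <- aln[, .(fragment_id, mate, pos)]
      setkey(other, fragment_id, mate)
      om <- other[J(aln$fragment_id, 3L - aln$mate)]
      rnext <- "="
      pnext <- om$pos + 1L
      leftmost <- aln$pos < om$pos | (aln$pos == om$pos & aln$mate == 1L)
      tlen <- ifelse(leftmost, aln$fragment_len, -aln$fragment_len)
    }
    recs <- paste(aln$read_id, flag, aln$chrom, aln$pos + 1L, aln$mapq,
                  aln$cigar, rnext, pnext, tlen, aln$seq_w, aln$qual_w,
                  paste0("XS:Z:", aln$bs_strand),
                  paste0("XO:Z:", aln$pseudo_chrom), sep = "\t")
  } else recs <- character(0)
  writeLines(c(hdr, recs), path)
  if (bam && requireNamespace("Rsamtools", quietly = TRUE)) {
    Rsamtools::asBam(path, sub("\\.sam$", "", path),
                     overwrite = TRUE, indexDestination = TRUE)
  }
  invisible(path)
}
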