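#' Read FASTQ file(s) into memory
#'
#' Accepts one or more (lane-split) FASTQ or FASTQ.gz files which are
#' concatenated in the given order.
#'
#' @param paths Character vector of FASTQ paths.
#' @return A list with character vectors \code{id}, \code{seq}, \code{qual}
#'   (phred+33).
#' @export
readFastqFiles <- function(paths) {
  parts <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("FASTQ file not found: ", p)
    # QualityScaledDNAStringSet construction warns about dropping the
    # (unused) metadata columns; that is expected here
    suppressWarnings({
      x <- Biostrings::readQualityScaledDNAStringSet(p)
      list(id = sub("\\s.*$", "", names(x)),
           seq = as.character(x),
           qual = as.character(Biostrings::quality(x)))
    })
  })
  list(id = unlist(lapply(parts, `[[`, "id"), use.names = FALSE),
       seq = unname(unlist(lapply(parts, `[[`, "seq"), use.names = FALSE)),
       qual = unname(unlist(lapply(parts, `[[`, "qual"), use.names = FALSE)))
}

#' @rdname readFastqFiles
#' @param reads A list as returned by \code{readFastqFiles}.
#' @param path Output path; a \code{.gz} suffix triggers gzip compression.
#' @export
writeFastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  n <- length(reads$id)
  if (n == 0L) { return(invisible(path)) }
  lines <- character(4L * n)
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- reads$qual
  writeLines(lines, con)
  invisible(path)
}

#' Trimming configuration
#'
#' Defaults: Illumina TruSeq adapter per mate, 3' quality threshold Q20
#' (running-sum rule), minimum post-trim length 36 nt, no extra head/tail
#' clipping.  Head/tail clipping is applied after adapter and quality
#' trimming: it targets end-repair artifacts of the insert itself (the
#' single-strand overhang problem), which survive adapter removal.
#'
#' @param adapter_r1,adapter_r2 3' adapter sequence per mate.
#' @param min_qual 3' quality threshold (phred).
#' @param min_len Pairs with either mate shorter than this after trimming
#'   are dropped entirely.
#' @param clip_head_r1,clip_tail_r1,clip_head_r2,clip_tail_r2 Extra cycles
#'   removed from read ends after adapter/quality trimming.
#' @param seed_len Exact adapter seed length.
#' @param max_mismatch_frac Mismatch tolerance over the matched adapter span.
#' @param min_overlap Minimum exact adapter overlap at the read 3' end.
#' @return A trim-configuration list.
#' @export
trimConfig <- function(adapter_r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       adapter_r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT",
                       min_qual = 20L, min_len = 36L,
                       clip_head_r1 = 0L, clip_tail_r1 = 0L,
                       clip_head_r2 = 0L, clip_tail_r2 = 0L,
                       seed_len = 8L, max_mismatch_frac = 0.1,
                       min_overlap = 3L) {
  list(adapter_r1 = adapter_r1, adapter_r2 = adapter_r2,
       min_qual = as.integer(min_qual), min_len = as.integer(min_len),
       clip_head_r1 = as.integer(clip_head_r1),
       clip_tail_r1 = as.integer(clip_tail_r1),
       clip_head_r2 = as.integer(clip_head_r2),
       clip_tail_r2 = as.integer(clip_tail_r2),
       seed_len = as.integer(seed_len),
       max_mismatch_frac = max_mismatch_frac,
       min_overlap = as.integer(min_overlap))
}

countStringMismatch <- function(a, b) {
  # a, b equal-length strings (vectors)
  mapply(function(x, y) sum(utf8ToInt(x) != utf8ToInt(y)),
         a, b, USE.NAMES = FALSE)
}

# 3' adapter position per read: index of first adapter base, or NA.
# Seed = exact match of the adapter's first seed_len bases anywhere in the
# read, validated over the full matched span at <= max_mismatch_frac
# mismatches; additionally, exact terminal overlaps of min_overlap..seed_len-1
# bases at the very read end are removed.
findAdapterStart <- function(seq, adapter, cfg) {
  len <- nchar(seq)
  seed <- substr(adapter, 1L, cfg$seed_len)
  pos <- regexpr(seed, seq, fixed = TRUE)
  hit <- as.integer(pos)
  cand <- which(hit > 0L)
  out <- rep(NA_integer_, length(seq))
  if (length(cand)) {
    span <- pmin(len[cand] - hit[cand] + 1L, nchar(adapter))
    a <- substr(seq[cand], hit[cand], hit[cand] + span - 1L)
    b <- substring(adapter, 1L, span)
    ok <- countStringMismatch(a, b) <= floor(cfg$max_mismatch_frac * span)
    out[cand[ok]] <- hit[cand[ok]]
  }
  # short exact overlap flush with the read end (longest first)
  for (L in seq(cfg$seed_len - 1L, cfg$min_overlap)) {
    todo <- which(is.na(out) & len >= L)
    if (!length(todo)) next
    m <- endsWith(seq[todo], substr(adapter, 1L, L))
    out[todo[m]] <- len[todo[m]] - L + 1L
  }
  out
}

# BWA-style 3' running-sum quality trim; returns kept length per read
qualityTrimLength <- function(seq, qual, thresh) {
  len <- nchar(seq)
  out <- len
  qsl <- phredToInt(qual)
  for (i in seq_along(qsl)) {
    q <- qsl[[i]]
    if (!length(q) || min(q) >= thresh) next
    s <- 0; smax <- 0; cut <- length(q)
    for (j in rev(seq_along(q))) {
      s <- s + (thresh - q[j])
      if (s < 0) break
      if (s > smax) { smax <- s; cut <- j - 1L }
    }
    out[i] <- cut
  }
  out
}

trimOneMate <- function(seq, qual, adapter, clip_head, clip_tail, cfg) {
  astart <- findAdapterStart(seq, adapter, cfg)
  keep <- ifelse(is.na(astart), nchar(seq), astart - 1L)
  seq <- substr(seq, 1L, keep)
  qual <- substr(qual, 1L, keep)
  qlen <- qualityTrimLength(seq, qual, cfg$min_qual)
  seq <- substr(seq, 1L, qlen)
  qual <- substr(qual, 1L, qlen)
  from <- pmin(clip_head + 1L, nchar(seq) + 1L)
  to <- pmax(nchar(seq) - clip_tail, 0L)
  list(seq = substr(seq, from, to), qual = substr(qual, from, to),
       adapter_found = !is.na(astart))
}

#' Trim read pairs (adapter, quality, head/tail clipping)
#'
#' Applies, in order: 3' adapter removal (seed match with mismatch
#' tolerance, plus short exact terminal overlaps), 3' quality trimming
#' (running-sum below \code{min_qual}), then fixed head/tail cycle clipping.
#' Pairs in which either mate falls below \code{min_len} are dropped
#' entirely (no singleton rescue).
#'
#' @param r1,r2 Read lists (\code{id}, \code{seq}, \code{qual});
#'   \code{r2 = NULL} for single-end data.
#' @param cfg A \code{\link{trimConfig}}.
#' @return A list: \code{r1}, \code{r2} (trimmed, kept pairs only),
#'   \code{clip_head_r1}, \code{clip_head_r2} (cycles removed at read 5',
#'   needed later for M-bias cycle attribution), \code{single_end}, and a
#'   \code{stats} list (\code{total_pairs}, \code{kept_pairs},
#'   \code{dropped_short}, \code{adapter_found},
#'   \code{base_composition_before/after}).
#' @export
trimReadPairs <- function(r1, r2 = NULL, cfg = trimConfig()) {
  single <- is.null(r2)
  n <- length(r1$seq)
  if (!single && length(r2$seq) != n)
    stop("mate files differ in read count")
  if (any(nchar(r1$seq) != nchar(r1$qual)))
    stop("malformed FASTQ: sequence/quality length mismatch in R1 at record ",
         which(nchar(r1$seq) != nchar(r1$qual))[1])
  if (!single && any(nchar(r2$seq) != nchar(r2$qual)))
    stop("malformed FASTQ: sequence/quality length mismatch in R2 at record ",
         which(nchar(r2$seq) != nchar(r2$qual))[1])
  compBefore <- list(r1 = baseComposition(r1$seq),
                     r2 = if (!single) baseComposition(r2$seq))

  t1 <- trimOneMate(r1$seq, r1$qual, cfg$adapter_r1,
                    cfg$clip_head_r1, cfg$clip_tail_r1, cfg)
  keep <- nchar(t1$seq) >= cfg$min_len
  adap <- t1$adapter_found
  if (!single) {
    t2 <- trimOneMate(r2$seq, r2$qual, cfg$adapter_r2,
                      cfg$clip_head_r2, cfg$clip_tail_r2, cfg)
    keep <- keep & nchar(t2$seq) >= cfg$min_len
    adap <- adap | t2$adapter_found
  }
  out1 <- list(id = r1$id[keep], seq = t1$seq[keep], qual = t1$qual[keep])
  out2 <- if (!single)
    list(id = r2$id[keep], seq = t2$seq[keep], qual = t2$qual[keep])
  stats <- list(
    total_pairs = n,
    kept_pairs = sum(keep),
    dropped_short = n - sum(keep),
    adapter_found = sum(adap),
    base_composition_before = compBefore,
    base_composition_after = list(r1 = baseComposition(out1$seq),
                                  r2 = if (!single) baseComposition(out2$seq)))
  list(r1 = out1, r2 = out2,
       clip_head_r1 = cfg$clip_head_r1, clip_head_r2 = cfg$clip_head_r2,
       single_end = single, stats = stats)
}

#' Per-cycle base composition
#'
#' Fraction of A/C/G/T/N at each sequencing cycle, among the reads that
#' reach that cycle.
#'
#' @param seqs Character vector of read sequences.
#' @return A data.frame with columns \code{cycle}, \code{A}, \code{C},
#'   \code{G}, \code{T}, \code{N} (fractions summing to 1 per cycle);
#'   zero rows for an empty input.
#' @export
baseComposition <- function(seqs) {
  empty <- data.frame(cycle = integer(0), A = numeric(0), C = numeric(0),
                      G = numeric(0), T = numeric(0), N = numeric(0))
  if (!length(seqs)) return(empty)
  seqs <- seqs[nchar(seqs) > 0L]
  if (!length(seqs)) return(empty)
  cm <- Biostrings::consensusMatrix(DNAStringSet(seqs))
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(0, nrow = 5, ncol = ncol(cm), dimnames = list(bases, NULL))
  for (b in intersect(bases, rownames(cm))) m[b, ] <- cm[b, ]
  tot <- colSums(m)
  frac <- t(m) / ifelse(tot == 0, 1, tot)
  data.frame(cycle = seq_len(nrow(frac)), frac, check.names = FALSE)
}
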