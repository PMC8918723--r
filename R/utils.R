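# Small shared helpers: sequence normalization, reverse complement on plain
# character vectors, CIGAR arithmetic, phred encoding.

normalizeSequenceLetters <- function(x) {
  # letters outside the A/C/G/T/N alphabet are replaced by N (one warning
  # per batch, as a count)
  bad <- gsub("[ACGTN]", "", x)
  nbad <- sum(nchar(bad))
  if (nbad > 0) {
    warning(sprintf("replaced %d non-ACGTN letter(s) by N", nbad),
            call. = FALSE)
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

# reverse complement of plain character sequences (keeps N)
revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

reverseString <- function(x) {
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

phredToInt <- function(qual) {
  # phred+33 string -> list of integer vectors
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

# ---- CIGAR -----------------------------------------------------------------

parseCigar <- function(cigar) {
  # returns list of data.frames (op, len); M/I/D/S/=/X/N supported
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  Map(function(cg, m) {
    toks <- regmatches(cg, list(m))[[1]]
    if (!length(toks) || any(is.na(toks)))
      stop("malformed CIGAR: ", cg)
    data.frame(len = as.integer(sub("[A-Z=]", "", toks)),
               op = sub("\\d+", "", toks), stringsAsFactors = FALSE)
  }, cigar, ops)
}

cigarRefSpan <- function(cigar) {
  out <- integer(length(cigar))
  fast <- isAllMatchCigar(cigar)          # overwhelmingly common case
  out[fast] <- as.integer(sub("M", "", cigar[fast], fixed = TRUE))
  if (any(!fast))
    out[!fast] <- vapply(parseCigar(cigar[!fast]), function(d) {
      sum(d$len[d$op %in% c("M", "D", "N", "=", "X")])
    }, integer(1))
  out
}

cigarReadSpan <- function(cigar) {
  vapply(parseCigar(cigar), function(d) {
    sum(d$len[d$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1))
}

reverseCigar <- function(cigar) {
  out <- cigar                            # all-M CIGARs are palindromic
  fast <- isAllMatchCigar(cigar)
  if (any(!fast))
    out[!fast] <- vapply(parseCigar(cigar[!fast]), function(d) {
      paste0(rev(paste0(d$len, d$op)), collapse = "")
    }, character(1))
  out
}

# Map read offsets (0-based, in the stored sequence) to reference offsets
# (0-based, relative to alignment start).  Insertions/soft-clips get NA.
cigarReadToRef <- function(cigar) {
  d <- parseCigar(cigar)[[1]]
  readoff <- integer(0)
  refoff <- integer(0)
  r <- 0L; g <- 0L
  for (i in seq_len(nrow(d))) {
    len <- d$len[i]; op <- d$op[i]
    if (op %in% c("M", "=", "X")) {
      readoff <- c(readoff, r + seq_len(len) - 1L)
      refoff <- c(refoff, g + seq_len(len) - 1L)
      r <- r + len; g <- g + len
    } else if (op %in% c("I", "S")) {
      readoff <- c(readoff, r + seq_len(len) - 1L)
      refoff <- c(refoff, rep(NA_integer_, len))
      r <- r + len
    } else if (op %in% c("D", "N")) {
      g <- g + len
    }
  }
  data.frame(read = readoff, ref = refoff)
}

isAllMatchCigar <- function(cigar) grepl("^\\d+M$", cigar)

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
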