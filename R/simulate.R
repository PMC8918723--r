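#' Simulation configuration
#'
#' Defaults describe a mammalian-like short-read methylation library:
#' 100 bp reads, fragment sizes N(167, 30) (nucleosome-protected cell-free
#' DNA scale), chemistry conversion rate 0.995 with inverse-failure 0.005,
#' substitution sequencing error 0.001, and an optional 5 kb fully
#' unmethylated lambda-like spike-in chromosome.
#'
#' @param genome_length Length of the random genome to generate.
#' @param n_fragments Number of fragments (read pairs, or reads when
#'   \code{paired = FALSE}).
#' @param read_len Read length in bp.
#' @param paired Paired-end?
#' @param frag_mean,frag_sd Normal fragment-size parameters (bp).
#' @param chem \code{"bisulfite"} or \code{"taps"}.
#' @param conversion_rate Probability that the chemistry converts the base
#'   it is supposed to convert (unmethylated C for bisulfite, methylated C
#'   for TAPS).
#' @param inverse_failure Probability of converting the base that should be
#'   left alone.
#' @param error_rate Per-base substitution sequencing error rate.
#' @param spike_in Include the unmethylated spike-in chromosome?
#' @param spike_in_length Spike-in chromosome length (bp).
#' @param ct_rich Restrict fragment starts to CT-rich windows of the
#'   template strand (regulatory-element-like low-complexity regions).
#' @param ct_min_fraction,ct_window CT-richness threshold and window size.
#' @param truth_betas \code{"beta"} draws per-CpG truth levels from
#'   Beta(0.5, 0.5) (bimodal, mammalian-like); a single number in [0,1]
#'   fixes a constant truth level.
#' @param seed Integer seed; all randomness in the simulator flows from it.
#' @return A simulation-configuration list.
#' @export
simConfig <- function(genome_length = 100000L, n_fragments = 10000L,
                      read_len = 100L, paired = TRUE,
                      frag_mean = 167, frag_sd = 30,
                      chem = c("bisulfite", "taps"),
                      conversion_rate = 0.995, inverse_failure = 0.005,
                      error_rate = 0.001, spike_in = FALSE,
                      spike_in_length = 5000L, ct_rich = FALSE,
                      ct_min_fraction = 0.7, ct_window = 200L,
                      truth_betas = "beta", seed = 1L) {
  chem <- match.arg(chem)
  rates <- c(conversion_rate, inverse_failure, error_rate)
  stopifnot(all(rates >= 0 & rates <= 1))
  list(genome_length = as.integer(genome_length),
       n_fragments = as.integer(n_fragments),
       read_len = as.integer(read_len), paired = paired,
       frag_mean = frag_mean, frag_sd = frag_sd, chem = chem,
       conversion_rate = conversion_rate,
       inverse_failure = inverse_failure, error_rate = error_rate,
       spike_in = spike_in, spike_in_length = as.integer(spike_in_length),
       ct_rich = ct_rich, ct_min_fraction = ct_min_fraction,
       ct_window = as.integer(ct_window), truth_betas = truth_betas,
       seed = as.integer(seed))
}

#' Simulate a random genome and per-CpG truth methylation table
#'
#' Generates an i.i.d. uniform A/C/G/T chromosome \code{"chr1"} (plus an
#' unmethylated lambda-like spike-in chromosome when requested) and assigns
#' every Watson CpG a truth methylation probability.  Spike-in CpGs are
#' fixed at 0.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @return A list: \code{ref} (\linkS4class{ReferenceGenome}), \code{truth}
#'   (\code{data.table} with \code{chrom}, \code{pos} 0-based Watson C,
#'   \code{beta}), \code{idx} (CpG index \code{GRanges}).
#' @export
simulateGenome <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  chr1 <- sample(bases, cfg$genome_length, replace = TRUE)
  if (cfg$ct_rich) {
    # pyrimidine-skewed blocks emulating CT-rich regulatory regions (a
    # uniform i.i.d. genome contains essentially no 200 bp windows at
    # C+T >= 0.7, so the CT-rich scenario plants them explicitly)
    nblock <- max(4L, cfg$genome_length %/% 5000L)
    blockLen <- 600L
    at <- sort(sample.int(cfg$genome_length - blockLen, nblock))
    for (a in at)
      chr1[a:(a + blockLen - 1L)] <-
        sample(bases, blockLen, replace = TRUE,
               prob = c(0.15, 0.30, 0.10, 0.45))
  }
  seqs <- c(chr1 = paste0(chr1, collapse = ""))
  if (cfg$spike_in)
    seqs <- c(seqs, lambda = paste0(
      sample(bases, cfg$spike_in_length, replace = TRUE), collapse = ""))
  ref <- ReferenceGenome(seqs, spikeIns = "lambda")
  idx <- buildCpGIndex(ref)
  chrom <- as.character(GenomeInfoDb::seqnames(idx))
  pos <- IRanges::start(idx) - 1L
  beta <- if (identical(cfg$truth_betas, "beta"))
    stats::rbeta(length(pos), 0.5, 0.5)
  else rep(as.numeric(cfg$truth_betas), length(pos))
  beta[chrom == "lambda"] <- 0
  truth <- data.table(chrom = chrom, pos = pos, beta = beta)
  list(ref = ref, truth = truth, idx = idx)
}

#' CT-rich windows of the Watson strand
#'
#' Sliding windows (stride = window/2) whose C+T fraction on the given
#' strand meets \code{min_fraction}; overlapping qualifying windows are
#' merged.  Such low-complexity (after C-to-T conversion) regions are
#' enriched in regulatory elements and stress alignment specificity.
#'
#' @param ref A \linkS4class{ReferenceGenome}.
#' @param min_fraction Minimum C+T fraction.
#' @param window Window length (bp).
#' @param strand \code{"watson"} (C+T counted on the given sequence) or
#'   \code{"crick"} (counted on the reverse complement, i.e. G+A on
#'   Watson).
#' @return A \code{data.table} of merged 0-based half-open intervals:
#'   \code{chrom}, \code{start}, \code{end}.
#' @export
findCtRichWindows <- function(ref, min_fraction = 0.7, window = 200L,
                              strand = c("watson", "crick")) {
  strand <- match.arg(strand)
  stride <- max(1L, window %/% 2L)
  out <- list()
  for (ch in chromNames(ref)) {
    s <- as.character(genomeSeqs(ref)[[ch]])
    L <- nchar(s)
    if (L < window) next
    isCT <- if (strand == "watson")
      strsplit(s, "")[[1]] %in% c("C", "T")
    else strsplit(s, "")[[1]] %in% c("G", "A")
    cum <- c(0L, cumsum(isCT))
    starts <- seq(1L, L - window + 1L, by = stride)
    frac <- (cum[starts + window] - cum[starts]) / window
    good <- starts[frac >= min_fraction]
    if (!length(good)) next
    ir <- IRanges::reduce(IRanges::IRanges(start = good,
                                           width = window))
    out[[ch]] <- data.table(chrom = ch,
                            start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
  }
  if (!length(out))
    return(data.table(chrom = character(0), start = integer(0),
                      end = integer(0)))
  rbindlist(out)
}

# apply chemistry to a template-strand fragment sequence.
# tmplCpG: logical, is this template position a CpG-context C whose truth
# beta is methProb (NA for non-CpG C).
applyChemistry <- function(chars, isC, methProb, cfg, rng) {
  conv <- logical(length(chars))
  cpg <- isC & !is.na(methProb)
  noncpg <- isC & is.na(methProb)
  methylated <- logical(length(chars))
  methylated[cpg] <- rng(sum(cpg)) < methProb[cpg]
  if (cfg$chem == "bisulfite") {
    # unmethylated C (CpG or not) converts at conversion_rate;
    # methylated C converts only through inverse failure
    unm <- (cpg & !methylated) | noncpg
    conv[unm] <- rng(sum(unm)) < cfg$conversion_rate
    conv[cpg & methylated] <- rng(sum(cpg & methylated)) < cfg$inverse_failure
  } else {
    # TAPS: methylated C converts at conversion_rate; unmethylated CpG C
    # converts through inverse failure; non-CpG C untouched
    conv[cpg & methylated] <- rng(sum(cpg & methylated)) < cfg$conversion_rate
    conv[cpg & !methylated] <-
      rng(sum(cpg & !methylated)) < cfg$inverse_failure
  }
  chars[conv] <- "T"
  chars
}

#' Simulate truth-tagged reads
#'
#' Samples fragments (uniformly, or from CT-rich windows of the template
#' strand when \code{cfg$ct_rich}), draws a per-molecule methylation state
#' for every CpG from the truth table, applies the chemistry (bisulfite:
#' unmethylated C to T; TAPS: methylated C to T; each with the configured
#' conversion/inverse-failure rates), cuts R1/R2 from the fragment ends
#' (with adapter read-through when the fragment is shorter than the read
#' length), and applies substitution sequencing errors.  Read IDs encode
#' the truth as \code{simN:chrom:start:end:strand}.
#'
#' @param ref,truth From \code{\link{simulateGenome}}.
#' @param cfg A \code{\link{simConfig}}.
#' @param adapter_r1,adapter_r2 Adapter sequences appended on read-through.
#' @return A list: \code{r1}, \code{r2} (read lists; \code{r2} NULL for
#'   SE), \code{truth_ids} (data.table of per-fragment truth).
#' @export
simulateReads <- function(ref, truth, cfg = simConfig(),
                          adapter_r1 = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                          adapter_r2 = "AGATCGGAAGAGCGTCGTGTAGGGAAAGAGTGT") {
  set.seed(cfg$seed + 1L)
  chroms <- chromNames(ref)
  lens <- chromLengths(ref)
  n <- cfg$n_fragments
  seqsChar <- as.character(genomeSeqs(ref))
  gchars <- lapply(seqsChar, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  compMap <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

  # per-chromosome truth lookup: full-length beta vector, NA off-CpG
  truthByChrom <- split(truth, truth$chrom)
  betaVec <- lapply(chroms, function(ch) {
    v <- rep(NA_real_, lens[[ch]])
    d <- truthByChrom[[ch]]
    if (!is.null(d)) v[d$pos + 1L] <- d$beta
    v
  })
  names(betaVec) <- chroms

  ctwin <- NULL
  if (cfg$ct_rich) {
    ctwin <- list(
      watson = findCtRichWindows(ref, cfg$ct_min_fraction, cfg$ct_window,
                                 "watson"),
      crick = findCtRichWindows(ref, cfg$ct_min_fraction, cfg$ct_window,
                                "crick"))
    ctwin <- lapply(ctwin, function(w) w[chrom %in% chroms])
    if (!nrow(ctwin$watson) && !nrow(ctwin$crick))
      stop("no CT-rich windows found; lower ct_min_fraction")
  }

  # fragment coordinates
  strand <- sample(c("+", "-"), n, replace = TRUE)
  size <- pmax(30L, as.integer(round(stats::rnorm(n, cfg$frag_mean,
                                                  cfg$frag_sd))))
  chromPick <- character(n)
  start <- integer(n)
  if (!cfg$ct_rich) {
    p <- lens / sum(lens)
    chromPick <- sample(chroms, n, replace = TRUE, prob = p)
    maxStart <- lens[chromPick] - size
    tooLong <- maxStart < 0L
    tries <- 0L
    while (any(tooLong)) {
      size[tooLong] <- pmax(30L, as.integer(round(
        stats::rnorm(sum(tooLong), cfg$frag_mean, cfg$frag_sd))))
      maxStart <- lens[chromPick] - size
      tooLong <- maxStart < 0L
      tries <- tries + 1L
      if (tries > 100L) stop("fragments repeatedly exceed chromosome length")
    }
    start <- as.integer(floor(stats::runif(n) * (maxStart + 1)))
  } else {
    for (i in seq_len(n)) {
      w <- if (strand[i] == "+") ctwin$watson else ctwin$crick
      if (!nrow(w)) { strand[i] <- if (strand[i] == "+") "-" else "+"
        w <- if (strand[i] == "+") ctwin$watson else ctwin$crick }
      row <- w[sample.int(nrow(w), 1L)]
      chromPick[i] <- row$chrom
      lo <- row$start
      hi <- min(row$end, lens[row$chrom] - size[i])
      if (hi < lo) { size[i] <- max(30L, row$end - row$start); hi <- lo }
      start[i] <- as.integer(lo + floor(stats::runif(1) * (hi - lo + 1)))
      if (start[i] + size[i] > lens[row$chrom])
        size[i] <- lens[row$chrom] - start[i]
    }
  }
  end <- start + size

  ids <- sprintf("sim%d:%s:%d:%d:%s", seq_len(n), chromPick, start, end,
                 strand)
  r1seq <- character(n)
  r2seq <- if (cfg$paired) character(n)
  rng <- stats::runif
  padA <- strrep("A", cfg$read_len)
  for (i in seq_len(n)) {
    fragChars <- gchars[[chromPick[i]]][(start[i] + 1L):end[i]]
    chars <- if (strand[i] == "+") fragChars
             else rev(unname(compMap[fragChars]))
    isC <- chars == "C"
    # map template C positions to Watson CpG sites
    mp <- rep(NA_real_, length(chars))
    if (any(isC)) {
      wc <- which(isC)
      tpos <- wc - 1L                              # 0-based in template
      gpos <- if (strand[i] == "+") start[i] + tpos
              else end[i] - 1L - tpos              # Watson coord of the C
      # CpG-context on the template strand: next template base is G
      nxt <- wc + 1L
      inCpG <- nxt <= length(chars) & chars[pmin(nxt, length(chars))] == "G"
      # Watson C position of the site: the C itself (+) or gpos-1 (the
      # Watson C pairing this Crick C)
      site <- if (strand[i] == "+") gpos else gpos - 1L
      b <- betaVec[[chromPick[i]]][pmax(site, 0L) + 1L]
      b[site < 0L] <- NA_real_
      mp[wc[inCpG & !is.na(b)]] <- b[inCpG & !is.na(b)]
    }
    chars <- applyChemistry(chars, isC, mp, cfg, rng)
    nf <- length(chars)
    r1 <- paste0(chars[seq_len(min(cfg$read_len, nf))], collapse = "")
    if (nf < cfg$read_len)   # adapter read-through
      r1 <- substr(paste0(r1, adapter_r1, padA), 1L, cfg$read_len)
    r1seq[i] <- r1
    if (cfg$paired) {
      rcChars <- rev(unname(compMap[chars]))
      r2 <- paste0(rcChars[seq_len(min(cfg$read_len, nf))], collapse = "")
      if (nf < cfg$read_len)
        r2 <- substr(paste0(r2, adapter_r2, padA), 1L, cfg$read_len)
      r2seq[i] <- r2
    }
  }

  addErrors <- function(seqs) {
    if (cfg$error_rate <= 0) return(seqs)
    m <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                nrow = cfg$read_len)
    hit <- which(stats::runif(length(m)) < cfg$error_rate)
    if (length(hit)) {
      repl <- sample(c("A", "C", "G", "T"), length(hit), replace = TRUE)
      same <- repl == m[hit]
      repl[same] <- chartr("ACGT", "CGTA", repl[same])  # force a change
      m[hit] <- repl
    }
    apply(m, 2, paste0, collapse = "")
  }
  r1seq <- addErrors(r1seq)
  qual <- strrep("F", cfg$read_len)   # Q37
  r1 <- list(id = ids, seq = r1seq, qual = rep(qual, n))
  r2 <- NULL
  if (cfg$paired) {
    r2seq <- addErrors(r2seq)
    r2 <- list(id = ids, seq = r2seq, qual = rep(qual, n))
  }
  list(r1 = r1, r2 = r2,
       truth_ids = data.table(id = ids, chrom = chromPick, start = start,
                              end = end, strand = strand))
}
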