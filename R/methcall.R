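#' Remove PCR duplicates
#'
#' Fragments sharing the duplicate key are collapsed to the one with the
#' highest summed base quality (ties: first encountered).  The key is
#' (chrom, fragment start, fragment end, bisulfite strand) for paired-end
#' data and (chrom, position, bisulfite strand) for single-end.  Input must
#' be coordinate-sorted (as produced by \code{\link{restoreAlignments}}).
#'
#' @param aln Restored alignment table.
#' @param minMapq Alignments below this MAPQ are counted as low-quality and
#'   excluded before duplicate marking (default 20).
#' @return A list: \code{alignments} (deduplicated table) and \code{stats}
#'   (\code{input_alignments}, \code{low_quality}, \code{duplicates_removed},
#'   \code{reported}; all counted per fragment).
#' @export
dedupAlignments <- function(aln, minMapq = 20L) {
  frag <- aln[, .(chrom = chrom[1], frag_start = frag_start[1],
                  frag_end = frag_end[1], pos = min(pos),
                  bs_strand = bs_strand[1], mapq = min(mapq),
                  single = fragment_len[1] == 0L,
                  sumqual = sum(vapply(qual_w, function(q)
                    sum(utf8ToInt(q)), numeric(1)))),
              by = fragment_id]
  bychrom <- split(frag$frag_start, frag$chrom)
  if (any(vapply(bychrom, is.unsorted, logical(1))))
    stop("alignments are not coordinate-sorted")
  nin <- nrow(frag)
  lowq <- frag[mapq < minMapq, fragment_id]
  frag <- frag[mapq >= minMapq]
  frag[, key1 := fifelse(single, pos, frag_start)]
  frag[, key2 := fifelse(single, -1L, frag_end)]
  frag[, ord := .I]
  setorder(frag, chrom, key1, key2, bs_strand, -sumqual, ord)
  keepIds <- frag[!duplicated(frag[, .(chrom, key1, key2, bs_strand)]),
                  fragment_id]
  ndup <- nrow(frag) - length(keepIds)
  out <- aln[fragment_id %in% keepIds]
  list(alignments = out,
       stats = list(input_alignments = nin,
                    low_quality = length(lowq),
                    duplicates_removed = ndup,
                    reported = length(keepIds)))
}

# Base observations of the Watson-oriented sequence at target positions.
# targetsW: positions (0-based, per chrom) observed by OT reads (Watson C);
# targetsC: positions observed by OB reads (Watson G = Crick C).
# Returns one row per (alignment, covered target) with the observed base,
# its quality and its original sequencing cycle.
baseObservations <- function(aln, targetsW, targetsC,
                             minQual = 20L, minMapq = 20L) {
  aln <- aln[mapq >= minMapq]
  empty <- data.table(chrom = character(0), pos0 = integer(0),
                      obs_strand = character(0), base = character(0),
                      qual = integer(0), mate = integer(0),
                      cycle = integer(0), fragment_id = integer(0),
                      is_spike_in = logical(0))
  if (!nrow(aln)) return(empty)
  aln <- copy(aln)
  aln[, row := .I]
  aln[, span := cigarRefSpan(cigar)]

  oneStrand <- function(sub, targets) {
    if (!nrow(sub) || !nrow(targets)) return(empty)
    setkey(targets, chrom, pos0)
    # fast path: pure-match CIGARs, offset = target - pos
    pure <- sub[isAllMatchCigar(cigar)]
    hits <- list()
    if (nrow(pure)) {
      tg <- split(targets$pos0, targets$chrom)
      for (ch in intersect(unique(pure$chrom), names(tg))) {
        p <- sort(tg[[ch]])
        sc <- pure[chrom == ch]
        lo <- findInterval(sc$pos - 0.5, p) + 1L
        hi <- findInterval(sc$pos + sc$span - 0.5, p)
        nper <- pmax(hi - lo + 1L, 0L)
        if (!sum(nper)) next
        h <- data.table(row = rep(sc$row, nper),
                        pos0 = p[sequence(nper, from = lo)])
        h <- merge(h, sub[, .(row, chrom, pos, mate, fragment_id,
                              is_spike_in, seq_w, qual_w, clip_head,
                              reversed_w)], by = "row")
        h[, off := pos0 - pos]
        hits[[length(hits) + 1L]] <- h
      }
    }
    gapped <- sub[!isAllMatchCigar(cigar)]
    if (nrow(gapped)) {
      for (i in seq_len(nrow(gapped))) {
        map <- cigarReadToRef(gapped$cigar[i])
        refpos <- gapped$pos[i] + map$ref
        want <- targets[chrom == gapped$chrom[i], pos0]
        m <- match(want, refpos)
        sel <- which(!is.na(m))
        if (!length(sel)) next
        h <- data.table(row = gapped$row[i], pos0 = want[sel],
                        chrom = gapped$chrom[i], pos = gapped$pos[i],
                        mate = gapped$mate[i],
                        fragment_id = gapped$fragment_id[i],
                        is_spike_in = gapped$is_spike_in[i],
                        seq_w = gapped$seq_w[i], qual_w = gapped$qual_w[i],
                        clip_head = gapped$clip_head[i],
                        reversed_w = gapped$reversed_w[i],
                        off = map$read[m[sel]])
        hits[[length(hits) + 1L]] <- h
      }
    }
    if (!length(hits)) return(empty)
    h <- rbindlist(hits, use.names = TRUE)
    h[, base := substr(seq_w, off + 1L, off + 1L)]
    h[, qual := utf8ToInt(paste0(substr(qual_w, off + 1L, off + 1L),
                                 collapse = "")) - 33L]
    h[, len := nchar(seq_w)]
    h[, cycle := clip_head + fifelse(reversed_w, len - 1L - off, off) + 1L]
    h[, .(chrom, pos0, base, qual, mate, cycle, fragment_id, is_spike_in)]
  }

  ot <- oneStrand(aln[bs_strand == "OT"], targetsW)
  ob <- oneStrand(aln[bs_strand == "OB"], targetsC)
  if (nrow(ot)) ot[, obs_strand := "W"]
  if (nrow(ob)) ob[, obs_strand := "C"]
  obs <- rbindlist(list(ot, ob), use.names = TRUE, fill = TRUE)
  obs <- obs[qual >= minQual]
  obs[]
}

cpgTargets <- function(idx) {
  pos <- IRanges::start(idx) - 1L
  chrom <- as.character(GenomeInfoDb::seqnames(idx))
  list(W = data.table(chrom = chrom, pos0 = pos, site = pos),
       C = data.table(chrom = chrom, pos0 = pos + 1L, site = pos))
}

# CpG observations, one row per (alignment, site); site = Watson C position.
cpgObservations <- function(aln, idx, minQual = 20L, minMapq = 20L) {
  tg <- cpgTargets(idx)
  obs <- baseObservations(aln, tg$W[, .(chrom, pos0)],
                          tg$C[, .(chrom, pos0)], minQual, minMapq)
  if (!nrow(obs)) {
    obs[, site := integer(0)]
    return(obs)
  }
  obs[, site := fifelse(obs_strand == "W", pos0, pos0 - 1L)]
  # valid observations only: C/T on the Watson C, G/A on the Watson G
  obs[(obs_strand == "W" & base %in% c("C", "T")) |
      (obs_strand == "C" & base %in% c("G", "A"))]
}

methylatedCall <- function(base, chem) {
  # Watson-oriented base at the cytosine of either strand: C (Watson) or G
  # (Crick) means the cytosine survived conversion, T or A means converted.
  retained <- base %in% c("C", "G")
  if (chem == "bisulfite") retained else !retained
}

#' Call per-CpG methylation
#'
#' Each deduplicated alignment contributes at most one observation per CpG
#' site: OT reads are read at the Watson C (C retained vs T converted), OB
#' reads at the Watson G, i.e. the Crick C (G retained vs A converted).
#' Under bisulfite chemistry a retained cytosine is methylated; under TAPS
#' the semantics invert (the chemistry converts methylated cytosines).
#' Overlapping mates of a pair observing the same site are counted once,
#' using the higher-quality base (tie: mate 1).
#'
#' @param aln Deduplicated restored alignment table.
#' @param ref The \linkS4class{ReferenceGenome}.
#' @param idx CpG index from \code{\link{buildCpGIndex}}.
#' @param chem \code{"bisulfite"} or \code{"taps"} (no default: the
#'   chemistry must be stated).
#' @param minQual Minimum base quality (default 20).
#' @param minMapq Minimum MAPQ (default 20).
#' @return A \code{data.table} with one row per covered CpG: \code{chrom},
#'   \code{pos} (0-based Watson C), \code{meth}, \code{unmeth}, \code{beta},
#'   strand-resolved \code{meth_watson}/\code{unmeth_watson}/
#'   \code{meth_crick}/\code{unmeth_crick}, and \code{is_spike_in}.
#' @export
callCpGs <- function(aln, ref, idx, chem = c("bisulfite", "taps"),
                     minQual = 20L, minMapq = 20L) {
  if (missing(chem))
    stop("the chemistry ('bisulfite' or 'taps') must be given explicitly")
  chem <- match.arg(chem)
  obs <- cpgObservations(aln, idx, minQual, minMapq)
  if (!nrow(obs))
    return(data.table(chrom = character(0), pos = integer(0),
                      meth = integer(0), unmeth = integer(0),
                      beta = numeric(0), meth_watson = integer(0),
                      unmeth_watson = integer(0), meth_crick = integer(0),
                      unmeth_crick = integer(0), is_spike_in = logical(0)))
  # overlapping PE mates at one site: higher quality wins, tie -> mate 1
  setorder(obs, fragment_id, chrom, site, -qual, mate)
  obs <- obs[!duplicated(obs[, .(fragment_id, chrom, site)])]
  obs[, meth := methylatedCall(base, chem)]
  calls <- obs[, .(
    meth = sum(meth), unmeth = sum(!meth),
    meth_watson = sum(meth & obs_strand == "W"),
    unmeth_watson = sum(!meth & obs_strand == "W"),
    meth_crick = sum(meth & obs_strand == "C"),
    unmeth_crick = sum(!meth & obs_strand == "C"),
    is_spike_in = is_spike_in[1]),
    by = .(chrom, pos = site)]
  calls[, beta := meth / (meth + unmeth)]
  setorder(calls, chrom, pos)
  calls[]
}

#' Write CpG calls as BED-like TSV / bedGraph
#'
#' @param calls Table from \code{\link{callCpGs}}.
#' @param path Output path.
#' @param format \code{"tsv"} (chrom, start, end, beta to 4 decimals, meth,
#'   unmeth, strand-resolved counts) or \code{"bedgraph"}.
#' @return Invisibly, the path.
#' @export
writeCpGCalls <- function(calls, path, format = c("tsv", "bedgraph")) {
  format <- match.arg(format)
  if (format == "tsv") {
    out <- data.frame(chrom = calls$chrom, start = calls$pos,
                      end = calls$pos + 2L,
                      beta = sprintf("%.4f", calls$beta),
                      meth = calls$meth, unmeth = calls$unmeth,
                      meth_watson = calls$meth_watson,
                      unmeth_watson = calls$unmeth_watson,
                      meth_crick = calls$meth_crick,
                      unmeth_crick = calls$unmeth_crick)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    out <- data.frame(chrom = calls$chrom, start = calls$pos,
                      end = calls$pos + 2L,
                      value = sprintf("%.4f", calls$beta))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Estimate the conversion rate from spike-in controls
#'
#' Over every cytosine of the spike-in chromosome(s) — both strands, all
#' sequence contexts — counts how many observations behave as the chemistry
#' predicts for unmethylated input: converted (T on Watson C / A on Watson
#' G) for bisulfite, retained (C / G) for TAPS.  A context breakdown (CpG
#' vs non-CpG cytosines) is reported; the all-context rate is the headline.
#'
#' @param aln Deduplicated restored alignment table.
#' @param ref The \linkS4class{ReferenceGenome} (its spike-in designation is
#'   used).
#' @param chem \code{"bisulfite"} or \code{"taps"}.
#' @param minQual,minMapq Quality filters as in \code{\link{callCpGs}}.
#' @return A list: \code{spike_in_names}, \code{estimable}, \code{rate},
#'   \code{converted_count} (observations behaving as predicted),
#'   \code{total_count}, and \code{by_context} (\code{cpg},
#'   \code{non_cpg} sublists).
#' @export
conversionRate <- function(aln, ref, chem = c("bisulfite", "taps"),
                           minQual = 20L, minMapq = 20L) {
  chem <- match.arg(chem)
  spikes <- spikeIns(ref)
  notEstimable <- list(spike_in_names = ref@spikeIns, estimable = FALSE,
                       rate = NA_real_, converted_count = 0L,
                       total_count = 0L,
                       by_context = list(
                         cpg = list(rate = NA_real_, total = 0L),
                         non_cpg = list(rate = NA_real_, total = 0L)))
  if (!length(spikes)) {
    warning("no spike-in chromosome present in the reference; ",
            "conversion rate not estimable")
    return(notEstimable)
  }
  seqs <- as.character(genomeSeqs(ref))[spikes]
  posC <- lapply(seqs, function(s) {
    m <- gregexpr("C", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  posG <- lapply(seqs, function(s) {
    m <- gregexpr("G", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  tW <- data.table(chrom = rep(spikes, lengths(posC)),
                   pos0 = unlist(posC, use.names = FALSE))
  tC <- data.table(chrom = rep(spikes, lengths(posG)),
                   pos0 = unlist(posG, use.names = FALSE))
  obs <- baseObservations(aln[is_spike_in == TRUE], tW, tC,
                          minQual, minMapq)
  obs <- obs[(obs_strand == "W" & base %in% c("C", "T")) |
             (obs_strand == "C" & base %in% c("G", "A"))]
  if (!nrow(obs)) {
    warning("zero usable spike-in observations; ",
            "conversion rate not estimable")
    return(notEstimable)
  }
  # CpG context: Watson C at a CG, or Watson G preceded by C
  cpgC <- lapply(seqs, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) integer(0) else as.integer(m) - 1L
  })
  cpgSet <- data.table(chrom = rep(spikes, lengths(cpgC)),
                       cpos = unlist(cpgC, use.names = FALSE))
  obs[, ckey := fifelse(obs_strand == "W", pos0, pos0 - 1L)]
  obs[, in_cpg := paste(chrom, ckey) %in% paste(cpgSet$chrom, cpgSet$cpos)]
  converted <- obs$base %in% c("T", "A")
  predicted <- if (chem == "bisulfite") converted else !converted
  rateOf <- function(sel) {
    tot <- sum(sel)
    list(rate = if (tot > 0) sum(predicted[sel]) / tot else NA_real_,
         total = tot)
  }
  list(spike_in_names = spikes, estimable = TRUE,
       rate = sum(predicted) / nrow(obs),
       converted_count = sum(predicted), total_count = nrow(obs),
       by_context = list(cpg = rateOf(obs$in_cpg),
                         non_cpg = rateOf(!obs$in_cpg)))
}

#' Methylation level per sequencing cycle (M-bias)
#'
#' Attributes every CpG observation to the original sequencing cycle of the
#' contributing base (undoing trimming offsets and Watson reorientation)
#' and reports the per-mate, per-cycle methylation level.  Artifacts such
#' as end-repair fill-in concentrate at read starts, most visibly at the
#' heading cycles of read 2.
#'
#' @inheritParams callCpGs
#' @return A \code{data.table}: \code{mate}, \code{cycle}, \code{meth},
#'   \code{unmeth}, \code{level}.
#' @export
mBias <- function(aln, ref, idx, chem = c("bisulfite", "taps"),
                  minQual = 20L, minMapq = 20L) {
  chem <- match.arg(chem)
  obs <- cpgObservations(aln[is_spike_in == FALSE], idx, minQual, minMapq)
  if (!nrow(obs))
    return(data.table(mate = integer(0), cycle = integer(0),
                      meth = integer(0), unmeth = integer(0),
                      level = numeric(0)))
  obs[, methylated := methylatedCall(base, chem)]
  tab <- obs[, .(meth = sum(methylated), unmeth = sum(!methylated)),
             by = .(mate, cycle)]
  tab[, level := meth / (meth + unmeth)]
  setorder(tab, mate, cycle)
  tab[]
}

#' Genome-wide and per-chromosome methylation levels
#'
#' Level = sum(meth) / sum(meth + unmeth), pooled over the CpGs of each
#' chromosome; spike-in chromosomes are excluded.  Chromosomes without a
#' covered CpG are omitted (recorded in the \code{omitted} attribute).
#'
#' @param calls Table from \code{\link{callCpGs}}.
#' @param ref The \linkS4class{ReferenceGenome}.
#' @return Named numeric vector of per-chromosome levels with attributes
#'   \code{overall} (genome-wide pooled level) and \code{omitted}.
#' @export
perChromosomeLevels <- function(calls, ref) {
  keep <- calls[is_spike_in == FALSE]
  chroms <- setdiff(chromNames(ref), spikeIns(ref))
  agg <- keep[, .(meth = sum(meth), tot = sum(meth + unmeth)), by = chrom]
  lv <- stats::setNames(agg$meth / agg$tot, agg$chrom)
  lv <- lv[intersect(chroms, names(lv))]
  overall <- if (nrow(agg)) sum(agg$meth) / sum(agg$tot) else NA_real_
  attr(lv, "overall") <- overall
  attr(lv, "omitted") <- setdiff(chroms, names(lv))
  lv
}
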