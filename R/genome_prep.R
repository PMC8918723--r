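#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzipped, multi-record) FASTA file, uppercases the
#' sequences and replaces any letter outside A/C/G/T/N by N (with a warning
#' giving the replacement count).  Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param spikeIns Chromosome names designated as unmethylated spike-in
#'   controls (default \code{"lambda"}).
#' @return A \linkS4class{ReferenceGenome}.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "acGTn"), fa)
#' loadFasta(fa)
#' @export
loadFasta <- function(path, spikeIns = "lambda") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- readDNAStringSet(path, format = "fasta")
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate chromosome name(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  chr <- normalizeSequenceLetters(toupper(as.character(seqs)))
  ReferenceGenome(stats::setNames(chr, names(seqs)), spikeIns = spikeIns)
}

#' Convert a genome-side sequence for alignment
#'
#' In \code{three_letter} mode every C becomes T (the classical
#' bisulfite-style alphabet reduction); in \code{four_letter} mode only a C
#' immediately followed by G is converted, preserving non-CpG cytosines and
#' thus sequence complexity (suited to TAPS-like chemistries).  A terminal C
#' or a C followed by N has unknowable/negative CpG context and is preserved
#' in four-letter mode.
#'
#' @param seq Character vector of sequences over A/C/G/T/N.
#' @param mode \code{"three_letter"} or \code{"four_letter"}.
#' @return Converted sequences, same lengths.
#' @examples
#' convertSequence("ACCGT", "three_letter")  # "ATTGT"
#' convertSequence("ACCGT", "four_letter")   # "ACTGT"
#' @export
convertSequence <- function(seq, mode = c("three_letter", "four_letter")) {
  mode <- match.arg(mode)
  if (mode == "three_letter") gsub("C", "T", seq, fixed = TRUE)
  else gsub("CG", "TG", seq, fixed = TRUE)
}

#' Build the converted Watson+Crick pseudo-genome
#'
#' For each chromosome X the pseudo-genome receives the converted Watson
#' sequence (named \code{X}) and the converted reverse complement (named
#' \code{X#rev}); \code{#} is illegal in ordinary chromosome names, so the
#' scheme cannot collide.  Mapping reads once against this reference
#' replaces the classical two-pass (Watson, then Crick) bisulfite alignment.
#'
#' @param ref A \linkS4class{ReferenceGenome}.
#' @param mode Conversion mode, see \code{\link{convertSequence}}.
#' @return A \linkS4class{PseudoGenome}.
#' @export
buildPseudoGenome <- function(ref, mode = c("three_letter", "four_letter")) {
  mode <- match.arg(mode)
  stopifnot(is(ref, "ReferenceGenome"))
  nm <- chromNames(ref)
  watson <- as.character(genomeSeqs(ref))
  crick <- revcompChar(watson)
  pseudo <- character(2L * length(nm))
  pnames <- character(2L * length(nm))
  pseudo[c(TRUE, FALSE)] <- convertSequence(watson, mode)
  pseudo[c(FALSE, TRUE)] <- convertSequence(crick, mode)
  pnames[c(TRUE, FALSE)] <- nm
  pnames[c(FALSE, TRUE)] <- paste0(nm, "#rev")
  origin <- data.frame(
    pseudo_name = pnames,
    orig_name = rep(nm, each = 2L),
    strand = rep(c("watson", "crick"), times = length(nm)),
    length = rep(unname(chromLengths(ref)), each = 2L),
    stringsAsFactors = FALSE)
  new("PseudoGenome", seqs = DNAStringSet(stats::setNames(pseudo, pnames)),
      origin = origin, mode = mode)
}

#' Index all Watson-strand CpG sites
#'
#' Scans every chromosome for CG dinucleotides and records the 0-based
#' position of the C.  By the palindromic nature of CpG the Crick-strand
#' cytosine of the same site sits at position + 1 (the Watson G).
#'
#' @param ref A \linkS4class{ReferenceGenome}.
#' @return A \link[GenomicRanges]{GRanges} of width-1 ranges at the Watson C
#'   of each CpG (1-based as usual for GRanges; the 0-based position is
#'   \code{start - 1}), with seqlengths set.
#' @export
buildCpGIndex <- function(ref) {
  stopifnot(is(ref, "ReferenceGenome"))
  hits <- Biostrings::vmatchPattern("CG", genomeSeqs(ref))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(chromNames(ref), S4Vectors::elementNROWS(hits)),
    ranges = IRanges::IRanges(start = unlist(IRanges::start(hits),
                                             use.names = FALSE),
                              width = 1L))
  GenomeInfoDb::seqlevels(gr) <- chromNames(ref)
  GenomeInfoDb::seqlengths(gr) <- unname(chromLengths(ref))
  gr
}

# 0-based CpG C positions for one chromosome, as an integer vector
cpgPositions0 <- function(idx, chrom) {
  as.integer(IRanges::start(idx[GenomeInfoDb::seqnames(idx) == chrom])) - 1L
}

#' Persist / reload a pseudo-genome index directory
#'
#' Writes the pseudo-genome FASTA, the origin table (TSV), the CpG index
#' (BED3, 0-based half-open) and a JSON manifest recording the conversion
#' mode, package version and per-file checksums.  \code{readGenomeIndex}
#' verifies the checksums and (optionally) the mode before reloading.
#'
#' @param pg A \linkS4class{PseudoGenome}.
#' @param idx CpG index \code{GRanges} from \code{\link{buildCpGIndex}}.
#' @param ref The \linkS4class{ReferenceGenome} the index was built from
#'   (persisted so that restoration and calling can reload it).
#' @param dir Output directory (created if needed).
#' @return \code{writeGenomeIndex}: the manifest (invisibly).
#'   \code{readGenomeIndex}: a list with elements \code{ref}, \code{pg},
#'   \code{idx}, \code{manifest}.
#' @export
writeGenomeIndex <- function(pg, idx, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("output directory not writable: ", dir)
  faP <- file.path(dir, "pseudo_genome.fa")
  faR <- file.path(dir, "reference.fa")
  orP <- file.path(dir, "origin.tsv")
  cgP <- file.path(dir, "cpg_index.bed")
  writeXStringSet(genomeSeqs(pg), faP)
  writeXStringSet(genomeSeqs(ref), faR)
  utils::write.table(originTable(pg), orP, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bed <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(idx)),
                    start = IRanges::start(idx) - 1L,
                    end = IRanges::start(idx))
  utils::write.table(bed, cgP, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  files <- c(pseudo_genome = "pseudo_genome.fa", reference = "reference.fa",
             origin = "origin.tsv", cpg_index = "cpg_index.bed")
  manifest <- list(
    format = "metharc-index",
    version = as.character(utils::packageVersion("metharc")),
    mode = conversionMode(pg),
    spike_ins = as.list(ref@spikeIns),
    checksums = lapply(files, function(f)
      unname(tools::md5sum(file.path(dir, f)))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @rdname writeGenomeIndex
#' @param mode If not NULL, the run's requested conversion mode; a mismatch
#'   with the stored index is a fatal error.
#' @export
readGenomeIndex <- function(dir, mode = NULL) {
  manP <- file.path(dir, "manifest.json")
  if (!file.exists(manP)) stop("not an index directory (no manifest): ", dir)
  manifest <- jsonlite::read_json(manP, simplifyVector = TRUE)
  if (!is.null(mode) && !identical(manifest$mode, mode))
    stop("index was built in ", manifest$mode,
         " mode but the run requests ", mode, " mode")
  for (nm in names(manifest$checksums)) {
    f <- file.path(dir, switch(nm,
      pseudo_genome = "pseudo_genome.fa", reference = "reference.fa",
      origin = "origin.tsv", cpg_index = "cpg_index.bed"))
    got <- unname(tools::md5sum(f))
    if (!identical(got, manifest$checksums[[nm]]))
      stop("checksum mismatch for ", basename(f),
           " (index corrupted or tampered)")
  }
  refSeqs <- readDNAStringSet(file.path(dir, "reference.fa"))
  names(refSeqs) <- sub("\\s.*$", "", names(refSeqs))
  ref <- ReferenceGenome(stats::setNames(as.character(refSeqs),
                                         names(refSeqs)),
                         spikeIns = unlist(manifest$spike_ins))
  pseqs <- readDNAStringSet(file.path(dir, "pseudo_genome.fa"))
  names(pseqs) <- sub("\\s.*$", "", names(pseqs))
  origin <- utils::read.table(file.path(dir, "origin.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE,
                              comment.char = "")  # '#' appears in names
  pg <- new("PseudoGenome", seqs = pseqs, origin = origin,
            mode = manifest$mode)
  idx <- buildCpGIndex(ref)
  list(ref = ref, pg = pg, idx = idx, manifest = manifest)
}
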