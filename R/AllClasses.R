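#' @import methods
#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet
#' @importFrom S4Vectors DataFrame
#' @importFrom data.table data.table setkey setorder rbindlist fifelse := .N
#'   .I .SD as.data.table copy setnames tstrsplit
NULL

#' ReferenceGenome: an original (unconverted) reference
#'
#' Thin container around a \link[Biostrings]{DNAStringSet} holding the
#' uppercase reference sequences plus the set of chromosome names designated
#' as unmethylated spike-in controls (lambda phage DNA by convention).
#'
#' @slot seqs A \code{DNAStringSet}, one entry per chromosome, alphabet
#'   restricted to A, C, G, T, N.
#' @slot spikeIns Character vector of chromosome names treated as spike-in
#'   controls for conversion-rate estimation (may name absent chromosomes,
#'   in which case estimation is flagged as not estimable).
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
         slots = c(seqs = "DNAStringSet", spikeIns = "character"))

setValidity("ReferenceGenome", function(object) {
  nm <- names(object@seqs)
  if (length(object@seqs) == 0L) return("genome has no chromosomes")
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    return("all chromosomes must be named")
  if (anyDuplicated(nm)) return("duplicate chromosome names")
  freq <- Biostrings::alphabetFrequency(object@seqs, baseOnly = FALSE)
  allowed <- c("A", "C", "G", "T", "N")
  bad <- setdiff(colnames(freq)[colSums(freq) > 0], allowed)
  if (length(bad))
    return(paste0("disallowed letters in genome: ", paste(bad, collapse = ",")))
  TRUE
})

#' Construct a ReferenceGenome
#'
#' @param seqs Named \code{DNAStringSet} or named character vector of
#'   sequences (uppercased on entry; letters outside A/C/G/T/N become N).
#' @param spikeIns Chromosome names to treat as spike-in controls.
#' @return A \linkS4class{ReferenceGenome}.
#' @export
ReferenceGenome <- function(seqs, spikeIns = "lambda") {
  if (is.character(seqs)) {
    seqs <- normalizeSequenceLetters(toupper(seqs))
    seqs <- DNAStringSet(seqs)
  }
  new("ReferenceGenome", seqs = seqs, spikeIns = as.character(spikeIns))
}

#' PseudoGenome: converted Watson+Crick alignment reference
#'
#' For every original chromosome the pseudo-genome holds two converted
#' pseudo-chromosomes: the converted Watson sequence under the original name
#' and the converted reverse complement (Crick) under \code{"<name>#rev"}.
#' Reads are aligned once against this reference; the origin table carries
#' the metadata needed to lift alignments back to Watson coordinates.
#'
#' @slot seqs \code{DNAStringSet} of pseudo-chromosomes.
#' @slot origin \code{data.frame} with columns \code{pseudo_name},
#'   \code{orig_name}, \code{strand} ("watson"/"crick") and \code{length}.
#' @slot mode \code{"three_letter"} (all C converted to T) or
#'   \code{"four_letter"} (CpG-context C only).
#' @exportClass PseudoGenome
setClass("PseudoGenome",
         slots = c(seqs = "DNAStringSet", origin = "data.frame",
                   mode = "character"))

setValidity("PseudoGenome", function(object) {
  if (!object@mode %in% c("three_letter", "four_letter"))
    return("mode must be 'three_letter' or 'four_letter'")
  o <- object@origin
  need <- c("pseudo_name", "orig_name", "strand", "length")
  if (!all(need %in% names(o))) return("origin table missing columns")
  if (!identical(o$pseudo_name, names(object@seqs)))
    return("origin table out of sync with sequences")
  if (!all(o$strand %in% c("watson", "crick")))
    return("origin strand must be watson/crick")
  if (!identical(as.integer(o$length),
                 unname(Biostrings::width(object@seqs))))
    return("pseudo-chromosome length differs from original")
  tab <- table(o$orig_name, o$strand)
  if (!all(tab == 1L))
    return("each chromosome must yield exactly one watson and one crick pseudo-chromosome")
  TRUE
})

#' QCBundle: aggregated run statistics feeding the HTML report
#'
#' A named list of per-stage statistics (trimming, alignment counts,
#' duplication, conversion rate, methylation summaries, M-bias, fragment-size
#' histograms, TSS profile, run metadata).  Every number rendered in the
#' report is sourced from this object.
#'
#' @slot stats Named list of statistics blocks.
#' @exportClass QCBundle
setClass("QCBundle", slots = c(stats = "list"))

setValidity("QCBundle", function(object) {
  nm <- names(object@stats)
  if (length(object@stats) && (is.null(nm) || any(nm == "")))
    return("all bundle entries must be named")
  TRUE
})

#' @export
QCBundle <- function(...) new("QCBundle", stats = list(...))

# ---- accessors -------------------------------------------------------------

#' @describeIn ReferenceGenome sequences as a DNAStringSet
#' @param x object
#' @export
genomeSeqs <- function(x) {
  stopifnot(is(x, "ReferenceGenome") || is(x, "PseudoGenome"))
  x@seqs
}

#' Chromosome names / lengths / spike-in designation
#'
#' @param x A \linkS4class{ReferenceGenome} or \linkS4class{PseudoGenome}.
#' @return Character vector of names, named integer lengths, or the
#'   spike-in name set.
#' @export
chromNames <- function(x) names(x@seqs)

#' @rdname chromNames
#' @export
chromLengths <- function(x) {
  stats::setNames(Biostrings::width(x@seqs), names(x@seqs))
}

#' @rdname chromNames
#' @export
spikeIns <- function(x) {
  stopifnot(is(x, "ReferenceGenome"))
  intersect(x@spikeIns, chromNames(x))
}

#' @describeIn PseudoGenome origin (back-mapping) table
#' @param x object
#' @export
originTable <- function(x) {
  stopifnot(is(x, "PseudoGenome"))
  x@origin
}

#' @describeIn PseudoGenome conversion mode
#' @export
conversionMode <- function(x) {
  stopifnot(is(x, "PseudoGenome"))
  x@mode
}

#' @describeIn QCBundle retrieve one statistics block (NULL if absent)
#' @param x object
#' @param name block name
#' @export
qcStat <- function(x, name) {
  stopifnot(is(x, "QCBundle"))
  x@stats[[name]]
}

#' @describeIn QCBundle all statistics as a named list
#' @export
qcStats <- function(x) {
  stopifnot(is(x, "QCBundle"))
  x@stats
}

setMethod("show", "ReferenceGenome", function(object) {
  cat("ReferenceGenome with", length(object@seqs), "chromosome(s),",
      sum(Biostrings::width(object@seqs)), "bp total\n")
  si <- spikeIns(object)
  cat("  spike-ins:", if (length(si)) paste(si, collapse = ", ") else "none",
      "\n")
})

setMethod("show", "PseudoGenome", function(object) {
  cat("PseudoGenome (", object@mode, ") with ",
      length(object@seqs), " pseudo-chromosome(s) from ",
      length(unique(object@origin$orig_name)), " chromosome(s)\n", sep = "")
})

setMethod("show", "QCBundle", function(object) {
  cat("QCBundle with blocks:", paste(names(object@stats), collapse = ", "),
      "\n")
})
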