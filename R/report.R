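#' Fragment-size distributions, target vs spike-in
#'
#' Histogram of paired-end fragment lengths in 1-bp bins, computed
#' separately for the DNA of interest and the spike-in control (whose size
#' profiles can differ markedly, e.g. for plasma cell-free DNA).  Single-end
#' data have no fragment length; the feature is skipped with a note.
#'
#' @param aln Restored (preferably deduplicated) alignment table.
#' @param maxLen Longest fragment binned (default 600 bp).
#' @return A list: \code{skipped} flag (with \code{note}), or \code{target}
#'   and \code{spike_in} data.tables (\code{size}, \code{count}).
#' @export
sizeDistribution <- function(aln, maxLen = 600L) {
  if (!nrow(aln) || all(aln$fragment_len == 0L))
    return(list(skipped = TRUE,
                note = "single-end data: no fragment size information"))
  frag <- aln[fragment_len > 0L,
              .(fragment_len = fragment_len[1],
                is_spike_in = is_spike_in[1]), by = fragment_id]
  histOf <- function(x) {
    x <- x[x >= 1L & x <= maxLen]
    data.table(size = seq_len(maxLen),
               count = tabulate(x, nbins = maxLen))
  }
  list(skipped = FALSE,
       target = histOf(frag[is_spike_in == FALSE, fragment_len]),
       spike_in = histOf(frag[is_spike_in == TRUE, fragment_len]))
}

#' Read a BED6 file of transcript start sites
#'
#' @param path BED6 path (chrom, start, end, name, score, strand).
#' @return A \code{data.table} with \code{chrom}, \code{tss} (0-based TSS
#'   position: \code{start} on +, \code{end - 1} on -), \code{strand}.
#' @export
readTssBed <- function(path) {
  if (!file.exists(path)) stop("TSS BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop("malformed BED (fewer than 6 fields) at line ", which(nf < 6L)[1])
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  strand <- vapply(parts, `[[`, "", 6L)
  bad <- is.na(start) | is.na(end) | !strand %in% c("+", "-")
  if (any(bad)) stop("malformed BED record at line ", which(bad)[1])
  data.table(chrom = vapply(parts, `[[`, "", 1L),
             tss = ifelse(strand == "+", start, end - 1L),
             strand = strand)
}

#' Methylation meta-profile around transcript start sites
#'
#' CpG calls within \code{[tss - flank, tss + flank)} are assigned to
#' \code{nbins} equal bins (minus-strand TSS mirrored so that transcription
#' always runs left to right) and averaged with coverage weights.  Active
#' promoters produce the characteristic methylation valley at the center.
#'
#' @param calls Table from \code{\link{callCpGs}}.
#' @param tss A \code{data.table} from \code{\link{readTssBed}} (or
#'   equivalent with \code{chrom}, \code{tss}, \code{strand}).
#' @param flank Half-window (bp, default 2000).
#' @param nbins Number of bins (default 100).
#' @return A \code{data.table}: \code{bin} (1-based), \code{offset}
#'   (bin-center offset from the TSS in bp), \code{meth}, \code{total},
#'   \code{level} (NA for bins without covered CpGs).
#' @export
tssProfile <- function(calls, tss, flank = 2000L, nbins = 100L) {
  binw <- 2 * flank / nbins
  out <- data.table(bin = seq_len(nbins),
                    offset = -flank + (seq_len(nbins) - 0.5) * binw,
                    meth = 0L, total = 0L)
  if (!nrow(calls) || !nrow(tss)) {
    out[, level := NA_real_]
    return(out[])
  }
  pieces <- vector("list", nrow(tss))
  for (i in seq_len(nrow(tss))) {
    d <- calls[chrom == tss$chrom[i] & pos >= tss$tss[i] - flank &
               pos < tss$tss[i] + flank]
    if (!nrow(d)) next
    rel <- d$pos - (tss$tss[i] - flank)
    bin <- pmin(as.integer(floor(rel / binw)) + 1L, nbins)
    if (tss$strand[i] == "-") bin <- nbins + 1L - bin
    pieces[[i]] <- data.table(bin = bin, meth = d$meth,
                              total = d$meth + d$unmeth)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces)) {
    agg <- rbindlist(pieces)[, .(meth = sum(meth), total = sum(total)),
                             by = bin]
    out[agg, on = "bin", `:=`(meth = i.meth, total = i.total)]
  }
  out[, level := fifelse(total > 0L, meth / total, NA_real_)]
  out[]
}

# ---- deterministic SVG helpers --------------------------------------------

svgNum <- function(x) formatC(x, format = "f", digits = 2)

svgLinePlot <- function(x, ys, labels, colors, width = 640, height = 280,
                        xlab = "", ylab = "", ymax = NULL) {
  pad <- 45
  ok <- vapply(ys, function(y) any(is.finite(y)), logical(1))
  ys <- ys[ok]; labels <- labels[ok]; colors <- colors[seq_along(ys)]
  if (!length(ys) || !length(x))
    return("<p class='note'>no data</p>")
  ymax <- ymax %||% max(unlist(ys)[is.finite(unlist(ys))], 1e-9)
  xmin <- min(x); xmax <- max(x); xr <- max(xmax - xmin, 1e-9)
  sx <- function(v) pad + (v - xmin) / xr * (width - 2 * pad)
  sy <- function(v) height - pad + (-v / ymax) * (height - 2 * pad)
  lines <- character(0)
  for (i in seq_along(ys)) {
    y <- ys[[i]]
    keep <- is.finite(y)
    pts <- paste(svgNum(sx(x[keep])), svgNum(sy(y[keep])), sep = ",",
                 collapse = " ")
    lines <- c(lines, sprintf(
      "<polyline fill='none' stroke='%s' stroke-width='1.5' points='%s'/>",
      colors[i], pts))
  }
  legend <- paste(sprintf(
    "<text x='%s' y='%s' fill='%s' font-size='11'>%s</text>",
    svgNum(width - pad - 120), svgNum(pad + 14 * seq_along(labels)),
    colors[seq_along(labels)], labels), collapse = "")
  axes <- sprintf(paste0(
    "<line x1='%1$s' y1='%4$s' x2='%3$s' y2='%4$s' stroke='black'/>",
    "<line x1='%1$s' y1='%2$s' x2='%1$s' y2='%4$s' stroke='black'/>",
    "<text x='%5$s' y='%6$s' font-size='11' text-anchor='middle'>%7$s</text>",
    "<text x='12' y='%8$s' font-size='11' transform='rotate(-90 12 %8$s)' ",
    "text-anchor='middle'>%9$s</text>",
    "<text x='%1$s' y='%10$s' font-size='10'>%11$s</text>",
    "<text x='%3$s' y='%10$s' font-size='10' text-anchor='end'>%12$s</text>",
    "<text x='40' y='%2$s' font-size='10' text-anchor='end'>%13$s</text>"),
    svgNum(pad), svgNum(pad), svgNum(width - pad), svgNum(height - pad),
    svgNum(width / 2), svgNum(height - 8), xlab,
    svgNum(height / 2), ylab,
    svgNum(height - pad + 14), svgNum(xmin), svgNum(xmax), svgNum(ymax))
  sprintf("<svg width='%d' height='%d' xmlns='http://www.w3.org/2000/svg'>%s%s%s</svg>",
          width, height, axes, paste(lines, collapse = ""), legend)
}

htmlTable <- function(df, digits = 4) {
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col))
      formatC(col, format = "g", digits = digits)
    else as.character(col)
  }
  body <- apply(as.data.frame(lapply(df, fmt)), 1, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>"))
  paste0("<table><thead><tr><th>",
         paste(names(df), collapse = "</th><th>"),
         "</th></tr></thead><tbody>", paste(body, collapse = ""),
         "</tbody></table>")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render the self-contained HTML report
#'
#' Emits a single HTML file with inline SVG figures (no external assets)
#' plus a TSV sidecar for every plotted/tabulated quantity.  All numbers
#' come from the \linkS4class{QCBundle}; nothing is computed in the
#' template layer, and the output is byte-identical for identical bundles
#' (timestamps are injected via the bundle's run metadata).
#'
#' @param bundle A \linkS4class{QCBundle}.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the path of \code{report.html}.
#' @export
renderReport <- function(bundle, outDir) {
  stopifnot(is(bundle, "QCBundle"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outDir, 2) != 0)
    stop("output directory not writable: ", outDir)
  s <- qcStats(bundle)
  sec <- character(0)
  addSec <- function(title, html) {
    sec <<- c(sec, sprintf("<h2>%s</h2>%s", title, html))
  }
  pct <- function(x) sprintf("%.2f%%", 100 * x)

  meta <- s$run %||% list()
  metaTab <- data.frame(field = names(meta),
                        value = vapply(meta, function(v)
                          paste(format(v), collapse = " "), character(1)))
  addSec("Run", htmlTable(metaTab))

  if (!is.null(s$trim)) {
    tt <- s$trim
    df <- data.frame(
      metric = c("total pairs", "kept pairs", "dropped (short)",
                 "adapter found"),
      value = c(tt$total_pairs, tt$kept_pairs, tt$dropped_short,
                tt$adapter_found))
    writeTsv(df, file.path(outDir, "trimming.tsv"))
    html <- htmlTable(df)
    for (m in c("r1", "r2")) {
      pre <- tt$base_composition_before[[m]]
      post <- tt$base_composition_after[[m]]
      if (is.null(pre) || !nrow(pre)) next
      writeTsv(pre, file.path(outDir, paste0("base_composition_before_",
                                             m, ".tsv")))
      writeTsv(post, file.path(outDir, paste0("base_composition_after_",
                                              m, ".tsv")))
      cols <- c(A = "#1b9e77", C = "#d95f02", G = "#7570b3", T = "#e7298a",
                N = "#666666")
      html <- paste0(html, sprintf("<h3>Base composition %s</h3>",
                                   toupper(m)),
        "<div>before: ",
        svgLinePlot(pre$cycle, as.list(pre[, c("A", "C", "G", "T", "N")]),
                    names(cols), unname(cols), xlab = "cycle",
                    ylab = "fraction", ymax = 1),
        " after: ",
        svgLinePlot(post$cycle,
                    as.list(post[, c("A", "C", "G", "T", "N")]),
                    names(cols), unname(cols), xlab = "cycle",
                    ylab = "fraction", ymax = 1), "</div>")
    }
    addSec("Read preprocessing", html)
  }

  if (!is.null(s$alignment)) {
    a <- s$alignment
    df <- data.frame(
      metric = c("input reads", "mapped reads", "mapping efficiency",
                 "fragments", "low-quality alignments", "PCR duplicates",
                 "reported fragments"),
      value = c(a$n_reads, a$n_mapped, pct(a$n_mapped / max(a$n_reads, 1)),
                a$dedup$input_alignments, a$dedup$low_quality,
                a$dedup$duplicates_removed, a$dedup$reported))
    writeTsv(df, file.path(outDir, "alignment.tsv"))
    addSec("Alignment and duplicates", htmlTable(df))
  }

  if (!is.null(s$conversion)) {
    cv <- s$conversion
    df <- if (isTRUE(cv$estimable)) data.frame(
      metric = c("spike-in", "conversion rate (all contexts)",
                 "conversion rate (CpG)", "conversion rate (non-CpG)",
                 "observations"),
      value = c(paste(cv$spike_in_names, collapse = ","), pct(cv$rate),
                ifelse(cv$by_context$cpg$total > 0,
                       pct(cv$by_context$cpg$rate), "n/a"),
                ifelse(cv$by_context$non_cpg$total > 0,
                       pct(cv$by_context$non_cpg$rate), "n/a"),
                cv$total_count))
    else data.frame(metric = "conversion rate",
                    value = "not estimable (no spike-in coverage)")
    writeTsv(df, file.path(outDir, "conversion_rate.tsv"))
    addSec("Spike-in conversion rate", htmlTable(df))
  }

  if (!is.null(s$methylation)) {
    mm <- s$methylation
    df <- data.frame(chrom = names(mm$per_chromosome),
                     level = unname(mm$per_chromosome))
    writeTsv(df, file.path(outDir, "per_chromosome_methylation.tsv"))
    html <- paste0("<p>Overall CpG methylation level: <b>",
                   pct(mm$overall), "</b></p>", htmlTable(df))
    addSec("Methylation levels", html)
  }

  if (!is.null(s$mbias) && nrow(s$mbias)) {
    mb <- s$mbias
    writeTsv(mb, file.path(outDir, "mbias.tsv"))
    series <- lapply(split(mb, mb$mate), function(d)
      d$level[order(d$cycle)])
    cyc <- sort(unique(mb$cycle))
    pad <- lapply(split(mb, mb$mate), function(d) {
      y <- rep(NA_real_, length(cyc))
      y[match(d$cycle, cyc)] <- d$level
      y
    })
    addSec("M-bias", svgLinePlot(cyc, pad,
                                 paste0("read ", names(pad)),
                                 c("#1f78b4", "#e31a1c"),
                                 xlab = "sequencing cycle",
                                 ylab = "methylation level", ymax = 1))
  }

  if (!is.null(s$sizes)) {
    sz <- s$sizes
    if (isTRUE(sz$skipped)) {
      addSec("Fragment sizes", sprintf("<p class='note'>%s</p>", sz$note))
    } else {
      writeTsv(sz$target, file.path(outDir, "size_target.tsv"))
      writeTsv(sz$spike_in, file.path(outDir, "size_spike_in.tsv"))
      addSec("Fragment sizes",
             svgLinePlot(sz$target$size,
                         list(sz$target$count, sz$spike_in$count),
                         c("target DNA", "spike-in"),
                         c("#1f78b4", "#e31a1c"), xlab = "fragment size (bp)",
                         ylab = "count"))
    }
  }

  if (!is.null(s$tss)) {
    if (isTRUE(s$tss$skipped %||% FALSE)) {
      addSec("TSS profile",
             "<p class='note'>not provided (no TSS annotation)</p>")
    } else {
      writeTsv(s$tss, file.path(outDir, "tss_profile.tsv"))
      addSec("Methylation around TSS",
             svgLinePlot(s$tss$offset, list(s$tss$level), "mean level",
                         "#1f78b4", xlab = "distance to TSS (bp)",
                         ylab = "methylation level", ymax = 1))
    }
  } else {
    addSec("TSS profile",
           "<p class='note'>not provided (no TSS annotation)</p>")
  }

  html <- paste0(
    "<!DOCTYPE html><html><head><meta charset='utf-8'/>",
    "<title>metharc report</title><style>",
    "body{font-family:sans-serif;margin:28px;max-width:900px}",
    "table{border-collapse:collapse;margin:10px 0}",
    "td,th{border:1px solid #bbb;padding:3px 9px;font-size:13px}",
    "h1{color:#234}h2{color:#345;border-bottom:1px solid #ccc}",
    ".note{color:#777;font-style:italic}",
    "</style></head><body><h1>metharc analysis report</h1>",
    paste(sec, collapse = ""), "</body></html>")
  out <- file.path(outDir, "report.html")
  writeLines(html, out)
  invisible(out)
}
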