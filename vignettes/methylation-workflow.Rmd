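---
title: "Single-pass methylation analysis with metharc: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-pass methylation analysis with metharc: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metharc)
```

# The model

## Chemistry

Both supported chemistries discriminate 5-methylcytosine by selective
C-to-T conversion, with opposite polarity:

* **bisulfite**: unmethylated C is deaminated and reads as T; methylated C
  survives. A retained C in a read is therefore evidence *for* methylation.
* **TAPS**: the methylated cytosine is the one converted; a retained C is
  evidence *against* methylation.

`metharc` treats the polarity as a single flag (`chem`) applied at calling
time. The observation model is identical for both: at a CpG site, an
original-top-strand (OT) read is inspected at the Watson C (C vs T) and an
original-bottom-strand (OB) read at the Watson G, which is the Crick-strand
C of the same palindromic site (G vs A after re-orienting the read to
Watson). Because the flag only relabels retained/converted as
methylated/unmethylated, swapping the chemistry on identical input must map
`(meth, unmeth)` to `(unmeth, meth)` at every site — an invariant the test
suite asserts exactly.

We deliberately refuse to guess the chemistry: `callCpGs()` has no default
for `chem` and the pipeline errors without it, because a silent wrong
default inverts every number in the output.

## The pseudo-genome and single-pass alignment

Conversion destroys Watson–Crick complementarity, so a converted read
matches only one strand's converted sequence. Rather than aligning each
read against two references, `metharc` concatenates both converted strands
into one reference: chromosome `X` (converted Watson) and `X#rev`
(converted reverse complement). The `#` separator cannot occur in ordinary
chromosome names, making back-mapping unambiguous.

Restoration is forced by the construction. Watson-origin hits keep their
coordinates (bisulfite strand OT). A hit at 0-based position $p$ with
reference span $s$ (from its CIGAR) on a Crick-origin pseudo-chromosome of
original length $L$ restores to Watson position $L - p - s$, with the CIGAR
reversed element-wise and sequence/qualities reverse-complemented/reversed
(strand OB). The arithmetic admits indel CIGARs; tests verify it against
reconstruction from the Watson sequence and a Needleman–Wunsch oracle.

An important consequence of carrying both strands: a *legitimate* converted
single-end read always matches some pseudo-chromosome in forward
orientation. A reverse-complement-only hit is chemically inconsistent and
is rejected; this is precisely how the single-pass design assigns strands.
For paired-end data, mate 2 is reverse-complemented and required to pair
with mate 1 in FR orientation on the same pseudo-chromosome.

## Conversion modes

* `three_letter`: every C→T in genome and reads (mate 2: G→A). Universal,
  but collapses the alphabet and with it alignment specificity.
* `four_letter`: only CpG-context cytosines convert (genome `CG`→`TG`;
  mate 1 C→T when followed by G; mate 2 G→A when preceded by C). Non-CpG
  cytosines retain their identity, which preserves complexity. This is the
  right mode for TAPS-like data, where non-CpG Cs survive the chemistry and
  would otherwise mismatch a fully converted reference.

Edge conventions, chosen conservatively: a C at a chromosome/read end, or
followed by N, has unknowable or negative CpG context and is **preserved**
in 4-letter mode; the mismatch allowance absorbs the rare cases. N runs in
the reference are retained verbatim (they break seed windows and never
match, which is the behaviour we want).

The 4-letter advantage is directional and mechanistic: two loci that are
identical after full C→T conversion but differ at non-CpG cytosines are
indistinguishable (multi-hit, hence unmapped under the unique-only policy)
in 3-letter space yet resolve uniquely in 4-letter space. The suite
constructs exactly this situation and also checks the inequality
(4-letter accuracy ≥ 3-letter) on CT-rich simulations. At the 100 kb desk
scale both modes are near-perfect, so the *gap* is small; the constructed
fixture is what demonstrates the mechanism deterministically.

# The built-in aligner

The package's aligner exists so the pipeline is fully testable without
external binaries; `externalAlign()` wraps bowtie2/hisat2 behind the same
interface when they are available. It is a classical exact-seed /
ungapped-extension design, implemented in C++:

* seeds: k-mers (default `k = 16`) from the read start at stride 4; seeds
  occurring more than `max_hits_per_kmer` (256) times in the pseudo-genome
  are skipped as repeats;
* extension: full-length ungapped mismatch count per candidate diagonal,
  with budget `max_mismatch_per100 = 4` scaled by read length (N never
  matches);
* pairing: FR on one pseudo-chromosome within `max_insert = 1000` bp,
  pair score = summed mismatches;
* ties: with `unique_only = TRUE` (default) a tied best score reports the
  read unmapped with the multi-hit flag — the conservative answer to the
  multi-mapping ambiguity that motivates the single-pass design. With
  `--random-tie`, one tied locus is chosen by a hash of (seed, global read
  index), which makes the choice reproducible *and* invariant to how reads
  are chunked across threads;
* MAPQ is a documented convention, not a probability model: 42 for unique
  hits, 0 for tie-broken ones (callers filter at MAPQ ≥ 20 by default, so
  tie-broken alignments never enter methylation calls).

The built-in aligner is ungapped; indel support lives in the restoration
and calling layers (exercised by synthetic CIGAR fixtures and available to
external-aligner output), which keeps the test aligner simple without
narrowing the data model.

# Preprocessing

Trimming applies, in order: 3′ adapter removal (8 nt exact seed anywhere in
the read validated at ≤10% mismatches over the matched span, plus exact
terminal overlaps down to 3 nt), 3′ quality trimming (running-sum rule at
Q20, the standard BWA-style criterion), then fixed head/tail clipping.
Clipping runs **after** adapter removal because it targets end-repair
artifacts of the insert itself (the single-strand overhang that depresses
apparent methylation at read-2 heads), which survive adapter trimming.
Pairs with either mate shorter than `min_len = 36` are dropped whole; there
is no singleton rescue. The head-clip counts are carried through alignment
so that M-bias can attribute every observation to its *original* sequencing
cycle.

# Calling, deduplication and QC

* **Duplicates**: key = (chrom, fragment start, fragment end, bisulfite
  strand) for PE, (chrom, position, strand) for SE; the copy with the
  highest summed base quality is kept (tie: first encountered). Alignments
  under MAPQ 20 are counted separately as low-quality, mirroring the
  report's separate accounting of low-quality, duplicate and reported
  alignments.
* **Calling filters**: base quality ≥ Q20, MAPQ ≥ 20. Overlapping mates of
  one fragment observing the same CpG contribute once — the
  higher-quality base wins, mate 1 on ties.
* **Conversion rate**: estimated over *all* cytosines of the spike-in
  chromosomes (both strands, all contexts), as the fraction of observations
  behaving as the chemistry predicts for unmethylated input (converted for
  bisulfite, retained for TAPS). The all-context rate is the headline and a
  CpG/non-CpG breakdown is reported, since the context split is the first
  thing to inspect when a library misbehaves. Zero coverage yields an
  explicit "not estimable" flag rather than a number.
* **M-bias**: per mate and original cycle, the methylation level of all CpG
  observations (no overlap collapsing — the two mates sample different
  cycles, and both are informative for cycle-level artifacts).
* **TSS profile**: CpG betas within ±2000 bp of each TSS in 100 bins,
  minus-strand TSS mirrored, coverage-weighted mean per bin; empty bins are
  reported missing (NA), never as zero.
* **Report**: a single self-contained HTML file with inline SVG generated
  deterministically by the package (fixed-precision coordinates, no
  rasterisation), every figure backed by a TSV sidecar, every number taken
  from the `QCBundle` — the template layer computes nothing. Timestamps and
  versions are injected through the bundle, so identical analyses render
  byte-identical reports. The full invocation echo (including thread count
  and paths) is persisted to `run_config.json`; the report embeds only the
  analysis-defining fields, which is what makes reports comparable across
  resource configurations.

# The simulator: what it emulates and what it does not

`simulateGenome()`/`simulateReads()` define the study conditions used
throughout the tests:

* i.i.d. uniform A/C/G/T genome (default 100 kb), optional 5 kb fully
  unmethylated lambda-like spike-in;
* per-CpG truth betas from Beta(0.5, 0.5) — bimodal like mammalian
  methylomes — or a constant; non-CpG cytosines are fully unmethylated
  (mammalian-like default);
* fragments Normal(167, 30) bp (nucleosome-scale), uniform strand, reads
  100 bp, adapter read-through when the fragment is shorter than the read;
* chemistry: conversion rate 0.995, inverse failure 0.005, applied per
  molecule after a Bernoulli(beta) methylation draw per CpG;
* substitution sequencing errors at 0.001 (no indel errors);
* read IDs carry the truth (`id:chrom:start:end:strand`), which is the
  interchange contract with `evaluateAgainstTruth()`.

For the CT-rich scenario, a uniform genome contains essentially no 200 bp
windows at C+T ≥ 0.7 (a ~5.7σ event), so requesting `ct_rich` plants
pyrimidine-skewed blocks (A/C/G/T at 0.15/0.30/0.10/0.45, 600 bp, roughly
one per 5 kb) emulating the CT-rich regulatory regions such benchmarks
target; fragments are then sampled from windows that are CT-rich on the
fragment's template strand (threshold 0.7, window 200 — documented
defaults).

What passing tests do show: coordinate arithmetic, strand assignment,
chemistry semantics, duplicate handling, estimator calibration (binomial
recovery of truth betas and conversion rates), and determinism are correct
under these conditions. What they do not show: robustness to real-world
quality profiles, indel sequencing errors, repeat structure of real
genomes, non-directional (PBAT) libraries, incomplete-conversion
heterogeneity along fragments, or hemimethylation — none of which the
generator models.

# Numerical and scale choices

Coordinates are 0-based half-open internally; SAM output is 1-based per the
format; CpG tables are BED-like 0-based. Betas are written to 4 decimals in
text outputs and kept at full precision in machine-readable ones. All
randomness descends from a single integer seed; outputs are byte-identical
across thread counts because read chunks merge in input order and per-read
tie-breaking hashes the global read index.

Test problem sizes were chosen so the whole suite exercises every claim at
meaningful depth yet runs in well under a minute: mapping round trips use
10,000 pairs on 100 kb, methylation recovery ~50× depth on 20 kb (~1,200
covered CpGs), restoration oracles 200 reads on 2 kb where exhaustive
substring search is feasible.

# Known limitations

* The built-in aligner is ungapped and end-to-end only (no soft clipping,
  no spliced alignment); reads spanning true indels are expected to go
  unmapped rather than misplaced, and indel-aware alignment requires the
  external-aligner path.
* Only CpG methylation is called; CHG/CHH cytosines enter the analysis
  solely through spike-in conversion counting.
* Directional libraries are assumed (R1 reads the converted strand);
  PBAT-style data would need the complementary read-side rules.
* MAPQ is categorical (42/0), not calibrated; downstream tools expecting
  probabilistic MAPQ should treat it as unique/ambiguous.
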