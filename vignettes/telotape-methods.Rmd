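---
title: "Telomere length profiling from long reads: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Telomere length profiling from long reads: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Human telomeres are terminal tracts of the 5'-TTAGGG-3' repeat, a few
hundred bases to well over 100 kb long. Long nanopore reads that run from
inside the subtelomere through the entire tract allow a *per-read, per-
molecule* length measurement: find where the telomeric repeat starts and
ends on the read, and anchor the unique subtelomeric part to a chromosome
arm. Each step fights a different source of noise — basecalling errors
inside a low-complexity repeat, interstitial telomere-like repeats
elsewhere in the genome, broken molecules, and subtelomere homology
between arms. `telotape` implements the full chain: repeat detection,
structural filtering, length calling, pangenome arm/allele anchoring, and
cohort statistics, plus a truth-known simulator that validates the whole
stack without any external data.

## Noise-tolerant repeat detection

A telomeric tract in a noisy read is modelled as a local alignment
between the read and an *unbounded tandem repetition* of the hexamer
motif. The dynamic program tracks, for every read position and every
cyclic motif phase, the best score of a local alignment ending there;
transitions are diagonal (base consumed against a motif character),
vertical (insertion in the read) and horizontal (deletion of a motif
character, cyclic within a row). Default scores are +1 match, −5
mismatch, −5 gap, with `N` scored as a mismatch (conservative). Because
gaps are strictly penalized, a deletion chain never profitably wraps the
whole motif, so each row reaches its fixpoint after a couple of sweeps.

Maximal segments are extracted iteratively: take the best cell (ties
resolved toward the smaller read position, then the smaller phase), trace
back with a fixed preference (diagonal > insertion > deletion) until the
score hits zero, record the candidate, mask its read interval, and
recompute the affected rows. Extraction stops when the best remaining
score falls below the minimum score any segment meeting the thresholds
could have (for the defaults, a 50 bp segment at 85% identity scores at
least 5). Candidates from the G-strand (TTAGGG) and C-strand (CCCTAA)
forms are pooled, overlaps resolved toward the higher score — ties going
to the form expected at the nearer read terminus, since a physical tract
has one orientation per terminus — and only then filtered by span
(≥ 50 bp) and identity (≥ 0.85). Resolving before filtering keeps the
emitted set monotone when the identity threshold is relaxed.

Because the motif has fixed length 6, the "full" wraparound DP is already
linear in the read length (6*n* cells), so no banding is needed: the
production implementation (C++) and the brute-force oracle used in the
test suite compute the same unbanded definition, the oracle naively in
pure R with its own traceback and resolution code. The segment-length
threshold is implemented as ≥ 50 bp (inclusive), with the threshold
exposed in configuration for users who prefer a strict reading.

## The three structure criteria

A read measuring a real chromosome end must (1) carry the motif in the
orientation of a terminus — the C-strand form opening the read or the
G-strand form closing it; (2) have that tract within 200 bp of the read
end; and (3) retain at least 60 bp of contiguous non-telomeric
(subtelomeric) anchor immediately interior to the tract, which excludes
molecules broken inside the repeat.

Criterion 1 and criterion 2 differ only in distance scale: a tract
1 kb from the read end is interstitial, one 250 bp away is a window
violation. We operationalize this with a coarse *terminal zone*
(`terminal_search`, default 500 bp): a correctly oriented tract whose
distal flank is within the zone is "terminal" (criterion 1 satisfied) and
then held to the strict 200 bp window (criterion 2); anything deeper in
the read has no terminal motif at all. Reads with qualifying tracts at
*both* termini are rare short fragments whose length cannot be
interpreted under a single-telomere model; they are rejected with a
dedicated `both_terminal` reason and logged. A configurable mean
base-quality floor (default Q9) is applied where qualities are available;
the threshold is a package default, surfaced in configuration, since
quality filtering regimes vary by basecaller.

All violated criteria are reported together (no short-circuiting), so a
defective read batch can be audited by reason.

## Length calling: the concatenation rule

Basecalling artifacts and variant repeats fragment a single biological
tract into several detected segments. Starting from the terminal-side
segment, segments of at least 50 bp are chained inward while the
breakpoint between neighbours is at most 250 bp; the chain stops at the
first larger break, and segments beyond it never contribute. Sub-50 bp
segments are treated as noise and removed *before* gaps are measured.

The called length is the *span* of the chain — first merged base to last,
including internal gaps — so that variant bases inside the tract count
toward telomere length; a sum-of-segments mode is available for
sensitivity analysis (`concat_params(length_mode = "sum")`). The span
choice reflects the view that the concatenated tract is one physical
repeat region with internal variation, not several.

## Pangenome anchoring

The reference is a collection of chromosome-end records from one or more
telomere-to-telomere assemblies: either the first and last 25 kb of every
contig (`mode = "end"`, with p = contig start by convention) or whole
contigs (`mode = "whole"`, appropriate for complete assemblies and for
the compact synthetic genomes used in validation). Each record carries a
telomere interval — located by running the repeat finder on the reference
itself — and the adjacent subtelomere interval. Haplotype labels are
parsed from contig names through an explicit token map.

Reads are aligned by any long-read aligner that reports secondary
alignments and soft-clips (the package wraps `minimap2 -x map-ont -N 2
-Y -L -a`); the package's own logic is the selection rule: a primary
alignment intersecting a telomere or subtelomere annotation is kept;
otherwise secondary alignments are scanned in deterministic order (MAPQ
descending, then file order, then record name) and the first
intersecting one is *promoted* to the read's assignment. Supplementary
alignments are never promoted, and promotion does not alter the read's
called length. Within a record, the arm whose combined
telomere-plus-subtelomere overlap with the alignment is largest wins.
Assignments are gated at MAPQ ≥ 20 (≥ 10 under the cancer profile, where
reference divergence is expected); allele-level assignment against a
phased reference uses a strict MAPQ > 5. Normalized per-arm coverage is
the fraction of MAPQ ≥ 20 assigned reads per arm.

One practical note: on a chromosome-end reference the telomeric repeat
dominates the minimizer table, and a *fractional* repeat filter keeps
exactly the seeds one wants discarded; the wrapper therefore applies an
absolute minimizer-occurrence cutoff (default 50) so alignments are
anchored by unique subtelomeric sequence.

## Haplotyping routes

With a phased diploid reference, the arm assignment already carries the
parental label of the contig; filtering at MAPQ > 5 yields
allele-labelled reads, and arms absent after filtering are reported
absent rather than zero-length. Without a phased reference, an external
variant-call/phase/haplotag toolchain (run against a haploid reference)
supplies per-read H1/H2 tags; these are joined to the pangenome
assignments keeping only reads that match exactly on read id,
chromosome, arm and strand — conflicting duplicates are dropped, and
unmatched reads stay in bulk tables untagged. The variant-calling stage
itself is an interface, not reimplemented; the test suite substitutes a
fixture haplotagger that tags reads from their known simulated allele.

## The simulator: what it emulates, and what it does not

`synthesize_genome_ends()` builds chromosomes of the form
`(CCCTAA)n + subtelomere + interior + subtelomere + (TTAGGG)n` with one
unique random subtelomere per arm (default 2.5 kb — long enough for
unambiguous anchoring at desk scale, far shorter than real 25 kb
subtelomeres) and tract lengths from a fixed, uniform or lognormal
sampler. Diploid mode plants substitutions between haplotype
subtelomeres (default 1 per 500 bp). Two technical guards keep the truth
well-defined: the subtelomere may not continue the repeat phase across
the junction (otherwise the planted tract boundary is ambiguous by
construction), and the junction window is kept free of the restriction
site so digestion never severs the anchor.

`simulate_reads()` emulates the library structure: per end, reads are
generated telomere-first, the tract is trimmed by a uniform 0–3000 bp
draw (trimming never eats the subtelomere; deeper draws truncate the
tract to zero), the molecule is virtually digested at EcoRV sites
(GAT^ATC, blunt; site and offset configurable) keeping the telomeric
fragment, per-base errors are injected at an average 2% with a
substitution:insertion:deletion mix of 50:25:25 (a nanopore-like profile;
only the average rate is a stated study condition, the mix is a package
default surfaced in configuration), and the read is reported on a random
strand. Thirty reads per end emulate 30× arm coverage; 23 chromosomes
give the 46 ends of a complete haploid assembly, 1380 reads in total.

The simulator does *not* model signal-space artifacts, context-dependent
error hotspots inside the repeat, basecaller-specific repeat compression,
real subtelomere homology families (acrocentric p-arms), or non-flat
quality strings. Passing round-trip validation therefore demonstrates
the correctness of the algorithmic chain under controlled noise, not
performance on real flow-cell data; the planted-homology fixtures show
how misalignment between homologous arms would surface in the confusion
matrix, but real homology structure is richer.

## Cohort statistics

Per-sample, per-arm and per-allele distributions are summarized by mean,
median, sample standard deviation (n−1 denominator — the TMM CV
thresholds shift only marginally under either convention), CV, IQR, and
the fractions strictly below 1 kb and strictly above 10 kb. Shortening
rates are ordinary least squares of mean length against population
doubling or donor age, reported with the 95% CI of the slope. The
subsampling model quantifies how mean-length precision scales with read
count via without-replacement subsampling. Arms are ranked by
within-sample z-scores of arm means, averaged across samples. Two-sample
comparisons use the two-sided independent t-test with Bonferroni
correction; Welch's variant is the default since per-sample variances
differ strongly in practice (a pooled option exists, and p-values from
the two variants can diverge on unbalanced designs). TMM classification
thresholds the CV of the per-read distribution: above 0.8 is ALT-like,
below 0.55 telomerase-like, with an explicit indeterminate band because
the thresholds are an observed separation on a small panel of cell
lines, not a validated decision rule; a minimum read count (default 100)
guards against classifying noise.

## Numerical and design choices

* Coordinates are 0-based half-open internally; SAM and BED conventions
  are converted at the boundary by the format libraries.
* Extraction tie-breaks, secondary-alignment ordering and region
  tie-breaks are all fixed and documented, making every output
  deterministic for a given input, configuration and seed; output tables
  carry the configuration's MD5 hash.
* Degenerate inputs are defined, not errors: empty read sets produce
  empty outputs with a warning, fully telomeric reads fail the anchor
  criterion with `anchor_length = 0`, trims deeper than the tract yield
  truth 0.
* Validation problem sizes (500 oracle reads up to 2 kb, 46 ends × 30
  reads, 200 regression replicates, 500 subsampling replicates, 50 TMM
  cohorts) were chosen to make sampling error negligible relative to the
  asserted tolerances while keeping the whole suite comfortable on a
  single CPU.

## Known limitations

* Arm assignment accuracy on real data is bounded by subtelomere length,
  inter-arm homology and sample-to-reference divergence; the synthetic
  subtelomeres are homology-free unless homology is planted, so the
  simulator's diagonal confusion matrices are a best case.
* The repeat finder targets the canonical hexamer; variant-repeat
  spectra (composition analysis) are out of scope, although variant
  bases inside a tract are counted toward its length by the span rule.
* Basecalling, methylation calling and the wet-lab protocol are out of
  scope; the package starts from basecalled FASTQ.
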