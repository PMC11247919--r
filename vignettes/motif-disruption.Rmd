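---
title: "Scoring variant effects on transcription factor binding motifs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring variant effects on transcription factor binding motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifdisrupt)
```

## The problem

Non-coding variants frequently act by changing how well a transcription
factor (TF) can bind a stretch of regulatory DNA. A TF's sequence
preference is commonly summarized as a position probability matrix (PPM): a
4 × k table giving, for each of the k positions of the binding site, the
probability of seeing A, C, G or T. `motifdisrupt` asks, for each variant
and each motif: *how good is the best motif match near the variant on the
reference allele, how good is it on the alternate allele, and how large is
the difference?*

Single-nucleotide variants (SNVs) are the classical case, but short
insertions and deletions — a substantial fraction of all variation — can
have larger effects: an insertion can split a binding site in two, or write
a complete new site into the genome. Both directions are modeled here, along
with multi-allelic sites, which are simply analyzed as independent ref/alt
pairs.

## The model

### Log-odds scoring

A PPM `p(b, j)` is turned into a log-odds score matrix against a background
model `bg` (default uniform):

```
score(b, j) = log2( max(p(b, j), floor) / bg(b) )
```

A k-mer's raw score is the sum of its per-position entries; `s_min` and
`s_max` are the sums of the column-wise minima and maxima. Reported scores
are min-max normalized, `(raw - s_min) / (s_max - s_min)`, so that the
consensus scores exactly 1 and the anti-consensus exactly 0 for every motif
regardless of its width or information content — this is what makes effect
sizes comparable across motifs.

The `floor` (default `1e-6`) replaces zero probabilities before the log.
Without it, any k-mer containing a base with probability zero would score
negative infinity; junction sequences created by indels would then be
unscoreable. Count matrices (JASPAR input) are smoothed on load with a total
pseudocount (default 0.8) split equally over the four bases per column, a
standard smoothing choice that keeps degenerate columns scoreable.

Ambiguous bases: an `N` in the scanned sequence contributes the
background-expected score of its column, which is unbiased and keeps windows
near assembly gaps usable. Windows with more than 20% ambiguous bases are
skipped with a warning.

### Allele windows

For a variant with reference allele span `[pos, pos + len(ref) - 1]` and a
motif of width k, the package extracts exactly `k - 1` bases of flank on
each side of the span, producing a reference window, and splices the
alternate allele into it for the alternate window. The flank length is not a
tuning knob: `k - 1` is precisely the set of motif placements that overlap
the variant. Any placement further away scores identically on both alleles
and cannot contribute an effect, so "best match in the whole sequence" and
"best match over all variant-overlapping placements" coincide. Windows are
truncated (never N-padded) at contig edges, because padding would inject
background-expected scores into real positions. Soft-masked lowercase bases
are uppercased on genome load.

### Best match, effect size, and classification

Each allele window is scanned on both strands (the minus strand via the
reverse-complemented matrix); the best placement per allele is kept, with
ties broken by lower position and then the plus strand so output is fully
deterministic. The effect size is

```
effect = score_ref - score_alt
```

in normalized units: positive means the alternate allele weakens the best
match (disruption), negative means it strengthens or creates one. Effects
with `|effect| >= strong_cut` (default 0.4) are classed `strong`, the rest
`weak`. The 0.4 default is this package's documented choice of a cutoff
large enough that, on a 0–1 scale, it corresponds to losing roughly half of
a site's dynamic range.

A variant × motif pair is reported when at least one allele's best match has
p-value at or below `p_threshold` (default `1e-4`, a conventional PWM-match
cutoff). The reported p-value is the per-k-mer p-value of the best match,
not a whole-sequence quantity corrected for the number of placements; this
is the package's fixed, documented choice.

### Exact match p-values

The p-value of a raw score is the probability that a random k-mer drawn
i.i.d. from the background scores at least as high. It is computed exactly
by convolving the per-position score distributions with dynamic programming:
after each position the attained partial sums are merged. While the state
count stays below `4^9` the attained values are kept exactly — the DP is
then exact to floating-point — and beyond that they are collapsed onto a
lattice of spacing `granularity` (default `(s_max - s_min) / 1e5`). Tail
queries treat scores within the accumulated lattice slack of the threshold
as qualifying, absorbing the bounded discretization error. Widths up to 9
therefore get exact p-values in this implementation; wider motifs get
lattice-resolution p-values with a known error bound. A 4^k brute-force
enumerator (`brute_force_pvalue()`, k ≤ 10) serves as an independent oracle
in the tests.

### Indel-relative motif coordinates

A motif created by an insertion has no reference-genome coordinates. Such
placements are located relative to the edges of the indel: the first number
is the displacement of the motif start from the variant's first base, the
second the displacement of the motif end from the variant's last base;
negative is upstream, positive downstream, and **0 means coincident with the
edge base** — a motif exactly coextensive with its insertion is `(0, 0)`.
The choice of 0 (rather than ±1) for the edge base is a convention this
package fixes and asserts in its tests; the opposite convention would shift
every offset by one. For deletions, the edges are defined on the deleted
reference segment, which keeps the coordinates genome-interpretable; the
alternate-window junction match is mapped across the deletion for this
purpose. For SNVs both coordinate forms describe the same placement and only
the genomic interval is reported.

### Variant normalization

VCF anchor bases are trimmed (shared leading bases first, then shared
trailing bases), multi-allelic records are split into one record per
alternate allele (ids suffixed `:1`, `:2`, …), and pure indels are
left-aligned against the genome until the preceding base differs, so that
identical indels written differently by different sources yield identical
results. Normalization is idempotent. Symbolic alleles (`<DEL>`, breakends)
are skipped with a warning; rsID lists are out of scope — records must
arrive pre-resolved in VCF or the 5-column BED-derived format
(`chrom start0 end0 name REF/ALT`, `-` for an empty side).

## Peak corroboration

Sequence preference alone over-predicts binding. To ground results in
observed binding, a local ChIP-seq peak database is built from a BED file
whose name field follows the `EXPERIMENT.TF.BIOTYPE` dotted convention of
ReMap-style non-redundant peak sets; parsing is right-anchored (last field =
biotype, second-to-last = TF) because experiment accessions may themselves
contain dots. Results are annotated by querying the variant's
reference-genome footprint (for pure insertions, the two flanking bases)
against the index: peaks of the same TF (case-insensitive) are *direct*
evidence; when there are none and a TF family map is supplied, peaks from
family members are *family* evidence; direct always pre-empts family. The
variant footprint — rather than the motif interval — is the default query
because the question asked is whether the TF binds over the disrupting
variant; the motif-interval alternative is available via
`query_by = "motif"`. The interval index is a `GRanges` overlap structure;
an optional serialized sidecar cache, keyed by the source file's checksum,
makes repeated builds of large peak sets cheap.

## Exports

`write_results_table()` produces a TSV/CSV with every field flattened
(indel-relative coordinates as `start,end`, peak evidence as match level,
count and semicolon-joined biotypes) and numeric fields at fixed 6-decimal
precision so diffs are reproducible. `write_results_bed()` produces a BED9
browser track of the reference-side matches; the display score is
`round(1000 × |effect|)` (score mode) or `round(1000 × (1 -
pvalue_min/p_threshold))` (p-value mode), and itemRgb follows a greyscale
ramp from `224,224,224` down to `0,0,0` — darker is stronger, and a
greyscale makes the monotonicity of the coloring testable channel-wise.
Results that pass the threshold only on the alternate allele (created
motifs, which have no reference coordinates) are routed to a companion table
instead of the BED.

## The synthetic fixture generator

`generate_fixtures()` builds a complete, seed-deterministic input bundle
with planted ground truth: strict-ish consensus motifs (consensus
probability 0.94, chosen high enough that the consensus is each column's
unique maximizer yet the matrix is not degenerate), a random background
genome, SNVs flipping a central consensus base (expected positive effect),
insertions writing a full consensus into background devoid of it (expected
negative effect, relative coordinates `(0, 0)`), one scenario for each of
the four ways an insertion can interrupt a motif (splice it apart, overlap
its start, contain it, overlap its end) with hand-enumerated coordinate
pairs, one multi-allelic site, and peaks over a known subset of variants
with matching, family-related and unrelated TF names. Default sizes — two
10 kb contigs, six motifs of widths 7–10, 24 disruptions, 6 creations — are
the package's chosen desk-scale study conditions: widths start at 7 because
a strict consensus match at width 6 has p-value `4^-6 ≈ 2.4e-4`, above the
default reporting threshold. Every manifest claim is verified at generation
time by direct string checks on the assembled windows and locally
re-randomized until it holds, so the bundle is valid by construction.

What the generator does *not* emulate: real motifs with uneven information
content, GC-biased or repetitive genomic background, overlapping variants,
haplotype phasing, and peak density patterns of real ChIP-seq compendia.
Passing the planted-truth tests therefore demonstrates the correctness of
the machinery — coordinates, signs, p-values, determinism — not calibration
of effect sizes on real data.

## A worked example

```{r example, eval = FALSE}
library(motifdisrupt)

bundle <- generate_fixtures(tempfile("fx"), seed = 7)
genome  <- read_genome(bundle$genome)
motifs  <- read_motifs(bundle$motifs)
variants <- read_vcf(bundle$variants, genome = genome)

results <- analyze_variants(variants, motifs, genome) |>
  attach_peak_evidence(build_peak_db(bundle$peaks),
                       fam = read_family_map(bundle$family_map))

glance(results)
autoplot(results)
```

## Numerical choices and edge cases

* Degenerate score range (`s_max == s_min`, e.g. a uniform motif): the
  normalized score is defined as 1 and the p-value distribution is a point
  mass.
* A threshold above every attainable score reports the probability of the
  top state rather than 0, keeping p-values in (0, 1].
* Tie-breaking everywhere is by lower position, then plus strand, with a
  locale-independent comparison.
* The reported strand is the reference allele's best strand unless only the
  alternate allele passes the threshold.
* Per-variant failures (missing contig, reference mismatch) are logged and
  skipped inside `analyze_variants()`; the command-line pipeline escalates a
  missing contig, or reference mismatches beyond `--max-ref-mismatch`
  (default 10%), to a non-zero exit because both usually mean the wrong
  genome build.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run at desk scale, chosen as
the package's own study conditions: the p-value oracle compares 30–50 random
motifs of widths 3–8 against full 4^k enumeration; path-equivalence and
symmetry properties use 100–200 random variants against libraries of 2–10
motifs on 3–13 kb toy genomes; the peak oracle compares 1,000 random queries
against a linear scan over 5,000 peaks; and the planted-truth checks run the
full pipeline on the default fixture bundle.

## Known limitations

* Zeroth-order background only; no first-order Markov background.
* One variant per window: nearby phased variants are not combined into
  haplotype windows.
* The p-value is per k-mer, not corrected for the number of placements
  scanned.
* Peak corroboration is evidence of binding in *some* assayed context, not
  cell-type-resolved confirmation.
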