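---
title: "Assessing assembly quality over immunoglobulin loci with igqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing assembly quality over immunoglobulin loci with igqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igqc)
```

## The problem

Immunoglobulin loci (IGH, IGK, IGL) carry large families of V, D and J
gene segments embedded in tandem duplications, and the two haplotypes of
a diploid individual often diverge strongly across them. Assemblers
struggle here even when genome-wide quality metrics look excellent, and
reference-based evaluators are of little help: there is usually no
suitable same-individual reference, and tools that assume a complete
diploid assembly misread the ~50% mismatch signal of a missing
haplotype as ordinary heterozygosity.

igqc evaluates these loci directly from the evidence that produced the
assembly: accurate long reads (HiFi-class, substitution error below
0.5%). If the assembly is correct, almost every read aligns to it almost
perfectly, at near-uniform depth. Two symptoms betray errors:

* **mismatch pile-ups** — reads that align somewhere with many
  substitutions because their true source sequence is absent from the
  assembly; the aligner parks them on the closest homolog, which also
  inflates local coverage;
* **coverage breaks** — positions spanned by almost no read, typically
  at false joins, false inversions, or scaffolding gaps.

## The metrics

Let `G` be the assembly and `R` the aligned reads. For a read `r`
aligned over `n(r)` bases, the substitution count against the assembly
is

```
d(r, G) = #{ aligned positions i : r_i != G_i },
e_r     = d(r, G) / n(r).
```

A read is *poorly aligned* when `e_r > theta`, with `theta = 0.01` by
default: an order of magnitude above the sequencing error rate, so a
flagged read is discordant with the assembly, not merely noisy.
Insertions, deletions and clipped bases are excluded from both `d` and
`n(r)` and tracked as separate channels (indel events are runs of >= 2
bp; clipping is reported per read). `n(r)` is the *aligned* length, not
the full read length, so `e_r` stays in [0, 1] and is insensitive to
clipping; a full-read denominator is available via
`compute_read_stats(denominator = "read")`.

Per assembly position `j`, with `J_j` the covering reads:

* **read-oriented count** `E_j = #{ r in J_j : e_r > theta }`.
  Position `j` is *poorly supported* when `E_j > 5` (strict). Six
  independent discordant reads cannot plausibly be sequencing noise.
* **basepair-oriented count** `delta_j = #{ r in J_j : r_j != G_j }`,
  with support fraction `(depth_j - delta_j) / depth_j`; positions with
  depth 0 are reported as missing, not as zero mismatch.
* **coverage breaks** are maximal runs of positions with depth <= 2.

A read deleted at `j` still counts toward `depth_j` (it spans the
position) but contributes neither match nor mismatch, so a break
genuinely means "no read spans here". Reads of every MAPQ contribute,
including MAPQ 0: multi-mapping reflects repeat structure and
inter-haplotype homology, not assembly error, so MAPQ is surfaced as
binned depth (60 / 1–59 / 0) rather than filtered. Secondary alignments
are dropped; supplementary alignments feed only read-level clip
statistics, never pileup depth, so a split read is not double-counted.

Breaks are classified by deterministic priority: `n_gap` (overlapping a
run of Ns — a scaffolding join lacking sequence), else `contig_end`
(within 5 kb of a contig boundary, where coverage tapers for geometric
reasons), else `zero_coverage`, else `low_coverage`. This taxonomy is
this package's reconstruction of break character from coverage and
reference sequence; it is a design choice, not an imported standard.

Gene-level calls follow the same two views: a gene is *read-affected*
when more than 5 poorly aligned reads overlap it by at least 1 bp
(genes are short relative to the reads, so any overlap attests), and
*base-affected* unless every gene position has depth > 0 and support
strictly above 80%. Strictness at the boundaries (0.01, 5, 2, 80%, 5)
follows the formal statements of the rules; figure-caption phrasings
that read as inclusive are noted in the parameter docs, and every bound
is configurable through `qc_options()`.

## Locus calls and cross-species summaries

Per locus class (union over its haplotype intervals), `call_locus()`
raises a **mismatch** flag when flagged positions clear an evidence
floor — one merged interval of >= 100 bp, or >= 0.5% of locus length —
and a **break** flag for any non-`contig_end` break of >= 10 bp; the
category applies precedence mismatch > break > good. These floors are
package-level defaults: they are set so that a defect-free simulation
is called "good" (isolated single-position flags should not condemn a
locus), and they are deliberately conservative for desk-scale data.
Survey tables of real assemblies never state per-species thresholds, so
this is a place where the package makes its own documented choice.

`aggregate_species()` tabulates one call per (species, locus) by locus
class and haplotype resolution. Published survey tables of this kind
count columns *non-exclusively* — a species with both error types
appears in both the mismatch and break columns, which is why printed
row counts can exceed group totals — so non-exclusive counting is the
default, with an exclusive mode (mismatch takes precedence) for
internally generated calls. Percentages are reported to 0.1% with
half-up rounding, matching report conventions; `good` always equals
`total - any_error` exactly in both modes.

## The synthetic fixture generator

Real IG loci span 1–2.5 Mb with 15–25 kb reads at ~30x; the generator
reproduces the error signatures at roughly 1/1000 of the compute:

| parameter | default | rationale |
|---|---|---|
| locus length | 120 kb per haplotype | large enough for mid-contig defects plus 5 kb end margins |
| gene cassettes | 8 x 6 kb tandem copies, 5% paralog divergence | tandem-duplicated V/D/J blocks |
| inter-haplotype divergence | 2% substitutions | IG loci are highly heterozygous |
| read length | mean 3.5 kb, sd 0.8 kb, min 1.5 kb | HiFi scaled down ~5x |
| read substitution error | 0.2% | below the 0.5% HiFi envelope |
| depth | 30x per haplotype | typical HiFi project coverage |

Reads are placed by an **oracle aligner** at their known origins with
recorded edits, so tests need no external binaries and per-read truth
is exact. Its behaviour at injected defects mirrors a long-read
aligner's handling of full-length reads:

* *missing segment* — the interval is deleted from one haplotype of the
  evaluated assembly while reads still come from the full genome; reads
  overlapping the deletion are placed full-length on the retained
  homolog at identity coordinates, where the 2% divergence sites become
  substitutions. This reproduces the missing-sequence signature: a
  cluster of poorly aligned reads plus locally elevated depth.
* *inversion with N-gap* — the interval is reverse-complemented with a
  run of Ns planted at the 5' breakpoint; reads crossing a breakpoint,
  or whose placement would overlap the N-run, are unplaceable and
  dropped, producing a coverage break that overlaps the planted gap.
* a read whose span contains no divergence site is ambiguous between
  haplotypes and gets MAPQ 0 (placed at its origin), exercising the
  MAPQ-0 handling without an aligner's arbitrary tie-breaking.

What the generator does **not** emulate: homopolymer-context indel
errors (the dominant residual HiFi mode), chimeric reads, coverage
biases, soft-clipped partial placements at defect boundaries (real
aligners clip; the oracle drops), and reference-scale repeat
complexity. Green tests therefore demonstrate that the detectors
recover the modelled signatures, not that they capture every failure
mode of real assemblies.

```{r fixture, eval = FALSE}
fx <- make_fixture("deletion", sim_config(seed = 1, locus_length = 60000,
                                          n_cassettes = 4, depth = 20))
ev <- evaluate_assembly(fx$assembly, fx$loci, fx$genes, fx$records)
ev$calls$IGH$category   # "mismatch"
```

## Validation properties

The shipped suite checks, per seed:

* **oracle equivalence** — every pileup column (depth, `delta_j`,
  `E_j`, MAPQ bins) equals an independent per-position recount done
  with plain loops, and the MD-tag fast path for `e_r` equals the
  base-by-base CIGAR walk for every read (100 kb loci at 30x, five
  seeds);
* **clean control** — simulating reads from the evaluated assembly
  itself (0.2% error, 25x, 100 kb per haplotype) yields a flagged
  fraction below 0.1% (observed: 0), no coverage break away from contig
  ends, no affected gene, and a "good" locus call;
* **defect recovery** — injected 20 kb missing segments are called
  "mismatch" with flagged intervals overlapping the homologous retained
  region at Jaccard >= 0.5 (observed ~0.8) and elevated local depth;
  injected 20 kb inversions with a 200 bp N-gap are called "break" with
  the detected break overlapping the gap and classified `n_gap`
  (60 kb loci at 20x, five seeds per defect).

Problem sizes were chosen so the default suite and the acceptance
script each run in minutes on one CPU; the signatures are insensitive
to scaling the locus up.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally everywhere; BED is
  consumed natively, mpileup and all human-facing tables are 1-based
  inclusive, with the dialect recorded in `#` header comments.
* Region strings (`contig:start-end`) follow the samtools dialect,
  1-based inclusive at both ends.
* Lowercase (soft-masked) assembly bases are uppercased before
  comparison; masking is not sequence difference. IUPAC codes other
  than N are rejected by default (`nonstandard = "mask"` converts them
  to N). Substitutions at reference-N positions are never counted:
  comparison to N is undefined.
* MD tags are trusted only when they tile the CIGAR's M/D extent
  exactly; otherwise the base-by-base walk is used. Records whose CIGAR
  and sequence lengths disagree are skipped with a warning count.
* Empty inputs degrade explicitly: an empty alignment stream yields
  all-zero pileup columns; an empty gene set yields a zeroed summary
  with a warning; empty flag sets write header-only tables.
* Plot overlays are taken verbatim from the flag/break tables (one
  metrics pass, serialized once); tests assert on exported overlay
  coordinates, never pixels. Heatmap bins default to 10 kb with weak
  positions defined as support <= 80%, consistent with the gene rule.

## Known limitations

Read-oriented metrics require per-read identity, so they are computed
from alignment records; mpileup ingestion (`load_mpileup()`) serves
only the basepair-oriented track. The locus-call evidence floors are
calibrated for the desk-scale regime and should be revisited for
megabase loci at higher depth. The simulator's equivalence to
simulations built on real references is a property target, not a claim
of identity, and CRAM input, realignment and assembly correction are
out of scope.
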