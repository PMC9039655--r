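---
title: "Detecting alien introgressions from exome-capture coverage drops"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alien introgressions from exome-capture coverage drops}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bread wheat is a large (~17 Gb) hexaploid whose cultivated genomes are
patchworks of introgressions — chromosome segments transferred from
progenitors and wild relatives — and deletions. Because whole-genome
sequencing at that scale is costly, accessions are routinely sequenced by
*exome capture*: hybridization probes enrich genic DNA before sequencing,
and reads are aligned back to a single reference assembly. That workflow
has a blind spot. Capture probes tolerate only a limited divergence from
their target (vendor figures are ~10–20%), and read aligners tolerate even
less, so a segment donated by a distant relative is doubly filtered: it may
fail to hybridize, and what is captured may fail to align. The visible
symptom is a *drop* in binned read coverage over the alien segment —
indistinguishable, at this level, from a deletion.

`introdrop` turns that observation into a tested, reusable pipeline. It
simulates the whole causal chain on synthetic mosaic genomes — reference,
diverged donors, mosaic accessions, gradient-placed probes,
divergence-dependent capture, paired-end reads, unique-only mapping,
zero-inclusive binned coverage — then detects drops cohort-relatively,
corroborates them with marker-genotype clustering, scores probe efficacy
in silico, and attributes unmapped reads to their donor of origin.

## The model, stage by stage

### Synthetic cohort

The reference genome is i.i.d. uniform DNA per chromosome with a declared
centromere. Donor genomes are derived from it by independent per-base
substitution at divergence $d$ (and optional geometric-length indels whose
edit tables allow exact coordinate lifting). Divergence tiers follow the
genepool structure of wheat's relatives: primary (progenitor-like,
$d = 0.015$), secondary ($d = 0.06$), tertiary (rye-like, $d = 0.12$).
The tier values are calibration choices — the true divergence of the real
donors from wheat is not known — picked to bracket the published capture
tolerances: primary donors sit well inside a 10% tolerance, tertiary ones
outside it.

A mosaic accession splices donor sequence over declared segments at
identical reference coordinates (perfect synteny, which the real loci
approximately satisfy) and excises `DELETION` segments while recording the
mosaic-to-reference coordinate lift. Outside its truth segments a mosaic is
base-identical to the reference, and the generators are pure functions of
their seed; both properties are tested.

Capture probes (120 bp) are placed with linear density
$1 + s\,u$ in the normalized distance $u$ from the centromere along each
arm, emulating the telomere-to-centromere gene-density gradient that real
capture designs inherit. The default slope $s = 3$ gives roughly a 4:1
telomere:centromere density ratio, a visually clear analogue of the
published coverage profiles.

Marker genotypes are biallelic categorical calls (two homozygotes,
heterozygote, missing). Accessions are simulated as inbred: inside an
introgression a marker is the alternative homozygote with probability 0.9
(else heterozygous, reflecting residual probe cross-hybridization), missing
inside deletions, and reference-homozygous elsewhere, before an error flip
(applied among the three genotype states; a deletion's `MISSING` status is
a physical absence, not a call error) and random masking.

### Capture and read simulation

For each probe the pipeline computes its *realized* divergence — the
per-base mismatch fraction between the probe and the homologous window of
the accession genome, with deleted bases counting as mismatches — and turns
it into a capture probability. Two forms are provided, because the
published tolerances are vendor thresholds rather than measured response
curves: a step model (capture iff $d \le T$, default $T = 0.10$) and a
logistic fall-off $1/(1 + e^{k(d-T)})$ with steepness $k = 80$, which puts
the probability above 0.99 at $d = 0$ and at 0.5 at the tolerance.

Using the realized (rather than expected) divergence has a consequence
worth stating: 120 bp windows inside a $d = 0.12$ segment fluctuate
binomially, so under the step model roughly a third of tertiary-segment
probes still capture. This is deliberate. It reproduces the real
observation that a sizeable minority of probes match a tertiary donor
assembly and that some alien fragments are captured yet fail to map — those
captured-but-unmappable reads are exactly what the attribution stage
recovers.

Captured probes emit $\mathrm{Poisson}(\lambda)$ read pairs: fragments
Normal(300, 30) bp truncated at the read length, centred on the probe with
uniform jitter, sequenced as 2 × 150 bp mates (mate 2
reverse-complemented) with i.i.d. substitution errors at $10^{-3}$
(a Q30-equivalent constant-quality model; quality-aware trimming is
modelled as a pass-through count). $\lambda$ is calibrated as
`mean_depth × probe_len / E[read bases on the probe per pair]`, where the
expectation is computed by deterministic numeric integration over the
fragment-length and jitter distributions, counting overlapping mates twice
because depth does. This makes the realized mean depth over probe bases
match the requested depth without empirical tuning.

### Mapping and the uniqueness criterion

Reads are mapped by exact k-mer seeds (default $k = 15$) and scored by
full-read ungapped Hamming distance on both strands. A locus is accepted if
its mismatch count is at most `max_mismatch_frac × read_len` (default
0.06); with disjoint seeds and a budget of 9 mismatches against 10 seeds,
the pigeonhole principle guarantees the seed search finds *every* accepted
locus, so the mapper is exactly equivalent to an exhaustive all-positions
scan (and is tested against one). A mate is *unique* iff its best locus
beats the second best by at least `unique_margin` (default 1) mismatches —
ties are never broken arbitrarily. A pair is "uniquely mapped, paired" iff
both mates are unique, on one chromosome, in forward/reverse orientation,
with an implied fragment within `frag_mean + 4·frag_sd`.

The mismatch budget of 0.06 sits between the primary (0.015) and tertiary
(0.12) divergence tiers on purpose: primary-segment reads map, tertiary
ones do not, which is the mechanism that converts divergence into coverage
drops. Ungapped comparison is also a choice: indel-bearing reads fall out
unmapped, consistent with diverged sequence failing to map back to the
reference; gapped comparison lives in the locus aligner instead.

### Coverage, normalization, drop calling

Depth counts read bases of uniquely mapped, properly paired mates only,
each mate independently. Means are taken over fixed-width bins *including
zero-coverage bases* (without zero inclusion, deletions simply vanish from
the profile); at the demo scale the 50 kb bins mirror the 5 Mb bins used at
full wheat scale. Each accession's bins are scaled by its genome-wide mean
depth (library size), then divided per bin by the cohort *median* of scaled
values. The median, not the mean, is the baseline so that a drop shared by
several carriers — as with the three carriers of the whole-arm rye
translocation — does not drag the baseline down with it. Bins whose cohort
median is zero (typically probe-free bins) are UNDEFINED: they get no
ratio, support no call, and break runs.

A drop call is a maximal run of at least `min_bins = 2` consecutive bins
with ratio below `alpha = 0.5`. Both values are invented defaults — the
original analysis called drops visually — and are exposed as arguments.
Calls are annotated against known intervals (a truth BED in simulation)
with overlap length and Jaccard index.

### Genotype clustering

Identity-by-state similarity between two accessions is the percentage of
comparable (both non-missing) markers with identical calls; zero comparable
markers yields UNDEFINED, never 0. Heterozygote calls are their own
category by default (a HET–HOM mismatch counts as a mismatch) — the
convention of the source analysis is unknown, so the choice is explicit
and configurable. Distances are $100 - \text{similarity}$; clustering is
UPGMA via average-linkage `hclust`, converted to an ultrametric `phylo`
tree whose node heights are half the merge distance (so cophenetic
distances reproduce ultrametric inputs exactly — tested, along with
agreement with two independent UPGMA implementations). Exact merge ties
follow `hclust`'s deterministic order; any tie order yields the same
heights. Restricting markers to a called drop splits carriers from
non-carriers into two clusters, and in-drop similarity to the reference
falls far below the rest of the chromosome — the direction of the
published in-interval vs chromosome-wide contrast.

### Probe efficacy and locus diagnosis

`probe_hits()` scores a probe set against a candidate assembly: a hit is a
word-seeded (11-mer), ungapped full-diagonal placement on either strand
covering ≥ 80% of the probe with identity (matches / probe length) ≥ 0.80.
The 0.80 floor echoes the widest published capture tolerance; the real
analysis used unstated local-search defaults, so the thresholds here are
explicit arguments. Because every query offset is seeded, the hit set
equals an exhaustive sliding-window oracle (tested). Hit counts and mean
best-hit identities fall monotonically with donor divergence — the in
silico signature of capture failing with evolutionary distance — and exact
duplications convert single-hit probes to multi-hit without changing the
number of probes with a hit.

`locus_align()` is Needleman–Wunsch global alignment with match +1,
mismatch −1, linear gap −2 (via Biostrings' aligner), with indel events
extracted from gap runs in the reference frame — the tool for diagnosing
small donor-haplotype insertions, such as a 3 bp and a 7 bp insertion that
distinguish a donor-derived resistance locus from the recipient copy.
`assign_nearest_reference()` aligns a captured query against candidate
references and votes by percent identity, returning `AMBIGUOUS` on exact
ties.

### Attribution of unmapped reads

Reads are classified against an explicit panel (reference + donor genomes)
with the same local-hit engine: label = best panel member if its identity
reaches 0.80, `AMBIGUOUS` if the top two lie within 0.02, else `NO_HIT`.
A small nucleotide panel replaces the large protein database of the
original analysis — at desk scale, with known donors, nucleotide-level
classification is exact and requires no downloads. The pipeline classifies
a capped sample (1,500 each) of unmapped mates and of mates uniquely
mapped to the carrier chromosome; the donor-attributed fraction among
unmapped reads exceeds that among mapped reads, the captured-but-unmapped
signature.

## Study conditions (the demo configuration)

`demo_config()` fixes the simulated study at 1:100 of wheat scale, chosen
once from the published magnitudes:

| quantity | value | full-scale analogue |
|---|---|---|
| chromosomes | 6 / 7 / 5 Mb (centromeres at 0.40/0.45/0.45) | 600/700/500 Mb |
| bin width | 50 kb | 5 Mb |
| probes | 2,016 (~112/Mb, 120 bp, slope 3) | ~27k probes per 240 Mb arm |
| accessions | 6 | 12 |
| tertiary segment | 2 carriers, whole 2.4 Mb short arm | 240 Mb arm translocation |
| secondary segment | 0.85 Mb on chr2L | 85 Mb drop |
| deletion + tertiary pair | 1.0 Mb each on chr3L | 40–45 Mb drops |
| primary segment | 0.3 Mb on chr2 | 25–30 Mb progenitor introgression |
| depth / reads | 20× over probe bases, 2 × 150 bp, 300 ± 30 bp fragments | |
| markers | 1,500 (~83/Mb) | 35k array |

The full run (`run_pipeline(demo_config(seed = 42))`) takes ~3 minutes on
one CPU; the test suite uses an additional miniature cohort (0.3 Mb-scale
chromosomes) for multi-seed property checks.

## What the simulation does and does not show

The generator reproduces the *geometry* of the real study: probe-density
gradients, segment sizes relative to bins, divergence tiers relative to
capture and mapping tolerances, deletion/introgression equivalence, and
carrier/non-carrier cohort structure. It deliberately omits repeat
families, polyploid homoeologues, GC bias, PCR duplicates, recombination,
and real gene annotation. Consequently, passing tests demonstrate that the
*method* — binning, cohort normalization, drop calling, clustering,
attribution — behaves correctly when its assumptions hold; they do not
certify performance on real wheat data, where homoeologous multimapping
and repeat content make unique mapping harder and where published
headline values (hit counts against real assemblies, similarity
percentages from real array data) depend on data this package does not
consume. The report layer's arithmetic (percentage and protein-length
bookkeeping) is reproduced exactly from the printed counts.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally and in BED;
  1-based inclusive only in human-readable output.
* Percentages round half-up to one decimal (`compute_percent()`), matching
  the reporting convention; a zero denominator is UNDEFINED (`NA`), not 0.
* `normalize_profiles()` refuses cohorts of fewer than 3 accessions — a
  median baseline is meaningless below that.
* Mapping ties (equal best mismatch counts at two loci) are non-unique by
  definition; no randomness exists anywhere in the mapper.
* The local-hit engine and its oracle compare identities with a 10⁻⁹
  tolerance so threshold-exact hits are kept on both sides.
* Empty inputs: an empty probe set yields an empty read set (not an
  error); an empty sequence aligns as all gaps with score `len × gap`;
  an empty known-interval list yields empty annotations.
* Per-stage seeds derive from the master seed by small fixed offsets,
  keeping every derived seed well below 2³¹.
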