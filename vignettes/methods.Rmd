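---
title: "Models and methods behind mycoTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mycoTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycoTE)
library(dplyr)
```

mycoTE implements the integrative regulatory-genomics workflow used to
characterise transposable elements (TEs) in fungal genomes such as the
arbuscular mycorrhizal fungus *Rhizophagus irregularis*: how old the TE
copies are, how CpG methylation is distributed over TEs and genes, how the
gene complement partitions into core, orphan and expanded classes, whether
particular TE families sit next to particular gene classes, and where small
RNAs (sRNAs) come from. This vignette explains each model, the parameters
that matter, the synthetic-data generator used to validate everything, and
the design decisions taken where more than one reasonable convention
exists.

## TE copy age: the CpG-adjusted Kimura two-parameter distance

Each annotated TE copy is aligned to its family consensus. Over alignment
columns where both sequences carry an unambiguous base, the transition
proportion $P$ and transversion proportion $Q$ give the Kimura (1980)
two-parameter distance

$$K = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right],$$

a proxy for the copy's age relative to the family's expansion. Two
conventions needed fixing explicitly:

* **CpG adjustment.** In methylated genomes, cytosines in CpG context
  deaminate at a much higher rate, so C→T / G→A transitions at consensus
  CpG sites mostly measure methylation-driven hypermutation, not age.
  Following the convention of the major repeat annotators, a transition at
  a column whose consensus base participates in a CpG dinucleotide (on the
  gap-stripped consensus) contributes weight 1/10 to the transition count.
  This choice never increases $K$, which one of the property tests asserts.
* **Saturation.** When $1-2P-Q \le 0$ or $1-2Q \le 0$ the distance is
  undefined; `kimura_distance()` raises a classed saturation error and the
  table-level `kimura_divergence()` flags the copy (`k = NA`) instead of
  failing a whole annotation.

The repeat landscape (`build_landscape()`) bins copies at 1
Kimura-percent resolution, bins 0–50 (values beyond 50 are clamped into the
last bin and counted), and accumulates genome coverage per superfamily per
bin. Copies are summed individually; overlapping copies are not collapsed,
so the landscape conserves total copy length exactly — also asserted in the
tests.

## Methylome scoring

Per-cytosine CpG calls arrive stranded. Since CpG methylation is
symmetric, the two strand records of one CpG are merged to a single site
keyed by the plus-strand C (0-based). The merged frequency is the
**coverage-weighted** mean — the two strands are two read samples of one
underlying state, so weighting by coverage is the natural pooled estimate
(an unweighted mean is the main alternative; the choice matters little at
even coverage but is stated so results are reproducible). Merging conserves
the total methylated-read mass exactly.

Per-interval methylation (`score_loci()`) is the **median** of site
frequencies in the interval — the `bedtools map -median` convention — with
the even-count median defined as the mean of the central pair. An interval
containing no CpG is *undefined*, never 0: treating CpG-free loci as
unmethylated would silently shift every downstream comparison. Intervals
are half-open, and a site exactly at an interval end is excluded.

Site-level bimodality (`classify_sites()`) reports the fractions of sites
above 0.8, below 0.2, and between, with strict inequalities at both
thresholds. Gene-level high/low labels use a strict `> 0.5` cut by
default; the cut is exposed as a parameter because published analyses
report the outcome (a percentage of highly methylated genes) without
printing the cut, so it must be explicit to be testable.

Metagene profiles pool sites over loci into 2-kb flanks in fixed 100-bp
bins and a 50-bin length-scaled body, reversing minus-strand loci so
upstream is always 5′. The per-bin value is the mean over all pooled
sites (each site counted once per overlapping locus).

## Gene classes

Classification is deterministic and ordered:

1. **transposon_related** — any domain label contains a blocklist token
   (reverse transcriptase, transposase, gag-pol, helitron helicase, ...),
   case-insensitively as a substring. Substring matching is deliberate:
   annotation pipelines decorate domain names with family suffixes
   (`Reverse_transcriptase_1`), and the blocklist mixes naming styles.
2. **crinkler** — candidate secreted effectors; on the (unlikely) gene
   carrying both a crinkler and an expanded-family domain, crinkler wins
   by default (configurable, conflicts counted) because effectors are
   treated as their own category.
3. **C_*** — the five expanded high-copy-number signalling families:
   serine/threonine/tyrosine kinases, calmodulin-dependent kinases,
   BTB/POZ, Sel1-like, Kelch-like. The calmodulin pattern is tested before
   the generic kinase pattern so CaM kinases are not swallowed by it.
4. **B_HCN / B_LCN** — orphans with no known domain, split purely by
   whether the gene overlaps a de novo repeat (`repeat_overlap`); no
   numeric copy-number cutoff is invented beyond that stated rule.
5. **A** — everything else: core genes with an identifiable domain.

Every gene receives exactly one class (a partition, asserted in tests).
Intergenic distances are gaps between adjacent gene bounds (0 on overlap,
`NA` at chromosome ends), oriented 5′/3′ by the gene's strand.

## TE–gene proximity statistics

`nearest_te()` reports, per gene, the classified TE with the smallest
edge-to-edge distance (strand-agnostic, 0 on any overlap), with ties broken
by leftmost TE start then smallest id so results are deterministic.
Edge-to-edge was chosen because the alternatives (gene start, TE midpoint)
are not stated in the analyses this reproduces; the choice is recorded
here rather than asserted as anyone's intent. Genes classified
`transposon_related` are excluded — they are themselves TE-derived and
would trivially self-match.

Distance distributions per gene class are compared to the core Class A
genes with the Kruskal–Wallis H test (tie-corrected, chi-square
approximation, via `stats::kruskal.test`), restricted per TE family.
Over-representation of a family as the *closest* element to a class uses a
two-sided Fisher exact test on the 2×2 table (class × closest-is-family),
with the p-value defined as the sum of hypergeometric probabilities not
exceeding that of the observed table and the sample odds ratio reported
with a Haldane (+0.5) correction when a cell is zero. `kw_dunn()` adds
Dunn's rank-based post hoc z comparisons against a reference group on
pooled tie-corrected ranks, Benjamini–Hochberg adjusted across the
reported family of comparisons — BH is applied within each such panel of
tests, not globally across the whole run, matching how per-figure analyses
are reported.

## Expression filters and the simplified differential test

"Normalised counts" means median-of-ratios size factors (the standard
robust library-size estimate for count matrices), computed over features
positive in all samples. The expressed-feature rules are applied at their
printed boundaries, strict where stated:

* TE subfamily: ≥ 100 normalised counts — read as "in at least one
  sample" by default since the sentence is ambiguous; a summed
  interpretation is available behind `subfamily_mode = "sum"`.
* TE locus: length **strictly** greater than 100 bp and RPKM ≥ 1 in ≥ 6
  samples.
* Gene: normalised count ≥ 2 in ≥ 2 samples.

TE copies overlapping an expressed gene are set aside as "genic" — their
apparent expression may be read-through — and downstream TE analyses use
the non-genic set.

`simple_de()` is deliberately simple: fold change
$\log_2\frac{\bar b + c}{\bar a + c}$ with pseudocount $c = 1$, p-value
from a pooled-variance two-sample t test on $\log_2(x + c)$, BH-adjusted,
significant iff $|\mathrm{log_2FC}| > 0.5$ and FDR $< 0.05$. There is no
dispersion shrinkage or count-model fit; that machinery is out of scope
here, and externally computed differential tables can be supplied wherever
one is consumed. The pooled (rather than Welch) t was chosen because on
the log scale the group variances are comparable for counts of similar
magnitude, and pooling preserves degrees of freedom in 3–4 replicate
designs; its operating characteristics on the generator's conditions
(false-positive control at FDR 0.05, sensitivity ≥ 0.9 at a planted
log2FC of 2) are measured in the acceptance tests, not assumed.

## Small RNA loci

`call_srna_loci()` is a simplified island clusterer driven by the printed
parameters of the published sRNA locus caller: reads pooled across
libraries, islands merged at gaps ≤ 200 bp (`pad`), islands kept when
their pooled count reaches 10 reads per million mapped (`mincov_rpmm`,
converted with the pooled total), strandedness at a majority share ≥ 0.8,
and a Dicer call when the count-weighted modal read length lies in 20–27
nt. The published tool's secondary-structure (fold-size) analysis is
deliberately not reimplemented — RNA folding is out of scope — so locus
boundaries can differ from that tool on real data; the printed parameters
are honoured exactly, which the boundary tests pin down. Clustering is
idempotent on its own output because retained islands are separated by
more than `pad`.

Treatment enrichment combines per-locus differential results for
periodate oxidation (which spares 2′-O-methylated sRNAs) and TraPR
purification (Argonaute-loaded sRNAs), each against untreated: enriched
iff significantly up in that assay, depleted iff significantly down in
either. The retained set drops only depleted loci by default; the stated
filtering rule in the source analyses is ambiguous between "drop
depleted" and "drop depleted plus never-enriched", so the stricter
alternative sits behind `drop_unenriched = TRUE` without asserting either
as the original intent.

Genomic origin is hierarchical: any ≥ 1 bp overlap with a classified TE
wins (larger overlap on conflict, exact ties to the expressed copy), then
expressed genes, then unannotated. Loci overlapping only non-expressed
genes deliberately fall through to unannotated and are counted, mirroring
the observation that sRNA loci do not arise from silent genes.

The shuffled-locus null re-places each locus uniformly at random —
chromosome drawn proportional to length among chromosomes the locus fits
on, start uniform, length preserved — and compares observed vs shuffled
nearest-TE distances with a Kruskal–Wallis test. Shuffled loci may overlap
annotations and each other: the null is "anywhere in the genome", with no
exclusion, and a single shuffle set of equal size is the default. The
shuffle is seeded and byte-reproducible.

## The synthetic-data generator

All statistical validation runs on `simulate_dataset()`, which plants
known truth:

* **Genome.** Two 1-Mb chromosomes of i.i.d. background (GC 0.30 — AT-rich
  like many fungal genomes; the background only needs a non-degenerate CpG
  density) plus a 20-kb designated mitochondrial contig, assembled from
  random gaps and feature blocks so annotation coordinates are
  byte-consistent with the FASTA.
* **TE copies.** ~500 copies in 8 families across the common superfamilies,
  each a consensus fragment mutated to a planted $K$: the expected
  $(P, Q)$ solving the K2P formula at a 2:1 transition:transversion ratio
  (no substitution model is stated for the organism; only the estimator
  matters downstream), substitution counts drawn binomially and placed
  uniformly without back-mutation. Recovery is therefore tested in
  expectation, with a stated tolerance (mean absolute error < 0.02 at
  $K \in \{0.05, 0.1, 0.2\}$ over ≥ 50 copies of ≥ 2 kb). Planted $K$
  values requiring $1 - 2P - Q < 0.05$ are rejected as saturated. Copy
  lengths are 15–50% of consensus, putting classified TEs at ~15% of the
  genome — a minor fraction, as in real fungal assemblies.
* **Genes.** ~800 genes over the ten classes with class-appropriate domain
  tokens; 60% of Class C genes are placed 50–1000 bp downstream of a MULE
  copy to plant the proximity signal.
* **Methylome.** Every CpG draws its methylation level from a
  Beta(50, 2) / Beta(2, 50) mixture with a per-feature-class probability of
  the high component (non-expressed TEs 0.95, expressed TEs 0.10, Class A
  gene bodies 0.05, orphans 0.5, background 0.3, mito 0.02), then two
  stranded records with binomial read noise at ~25× coverage.
* **sRNA.** Loci from young TEs ($K < 0.1$, 70% of them), plus genic loci
  in TE-adjacent expressed genes and unannotated loci planted 5–150 bp
  from TE copies — non-TE sRNA sources sit in the vicinity of TEs, which
  is exactly the association the shuffle-null analysis is designed to
  detect — plus abundant mitochondrial contaminant loci. Reads have a
  24-nt-peaked length distribution and 5′ nucleotide probabilities
  (U 0.5, A 0.3, C 0.1, G 0.1); truly enriched loci are multiplied by 4 in
  the corresponding treated libraries and mitochondrial loci by 0.05 in
  both. Three replicates per library feed the enrichment test.
* **Counts.** Negative-binomial (dispersion 0.05) matrices for genes, TE
  loci and TE subfamilies over the five developmental conditions (0 h;
  24 h and 48 h, mock and exudate) × 4 replicates. Subfamily resolution is
  5 subfamilies per family (40 features) with 3 planted at log2FC = 2 in
  the exudate conditions, keeping the differential fraction small enough
  that median-of-ratios normalisation stays anchored on null features.
  Non-expressed features have mean zero, so planted expression flags are
  exact.

Effect sizes for "young TEs produce more sRNA" and the enrichment factor
are free parameters — no quantitative values are published — chosen once
at magnitudes a small-RNA practitioner would call clear but not extreme
(probability 0.7, factor 4) and not revisited.

What the generator does **not** emulate: sequencing error, mappability and
multi-mapping ambiguity, indels in TE copies (alignments are gapless),
linked methylation along reads, overdispersion structure beyond a single
NB dispersion, and genome composition beyond uniform background. Passing
tests therefore demonstrate correctness of the estimators and decision
rules under their stated assumptions, not robustness to alignment or
calling artefacts in real data.

## Randomness, problem sizes and degenerate inputs

Every stochastic stage derives from the single integer seed in
`sim_config()`; generators use fixed offsets of it (`withr::with_seed`)
so each stage is independently reproducible, and two runs of
`run_pipeline()` with one config are identical — asserted byte-for-byte in
the tests. The reference problem size (2-Mb genome, ~500 copies, ~800
genes, ~50k reads across libraries) runs end-to-end in well under a
minute; unit tests use a 0.4-Mb scaled configuration. Degenerate inputs
have defined behaviour throughout: empty landscapes are all-zero,
CpG-free loci are undefined rather than 0, all-identical samples give
H = 0 and p = 1, groups below two observations are skipped and flagged,
and malformed intervals or duplicated identifiers fail fast with named
errors.

## Interfaces

The package is tidyverse-shaped: every analysis function takes a data
frame and returns a tibble, so stages chain with the pipe;
`run_pipeline()` orchestrates all stages in memory and
`write_pipeline_results()` serialises the result tables as TSV. Readers
and writers cover FASTA (via Biostrings), RepeatMasker `.out`, BED6, GFF3
with a `domains` attribute (1-based inclusive on disk, 0-based half-open
in memory; conversion happens only at the I/O boundary), and the TSV
dialects for methylation calls, sRNA reads and count matrices. Test
objects (`kw_dunn()`, `simple_de()`, `shuffle_null_distance()`) follow
broom conventions (`tidy()`, `glance()`) and have `autoplot()`/`plot_*()`
companions.
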