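---
title: "Inferring a GlnR nitrogen regulon: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring a GlnR nitrogen regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glnregulon)
```

# The inference problem

GlnR is the OmpR-family master regulator of nitrogen metabolism in
actinomycetes. Its regulon is defined here by combining three kinds of
evidence collected over a nitrogen-starvation time course (T0 mid-log on
ammonium, T30 after 30 min of nitrogen starvation, T45 after 15 min of
ammonium re-addition):

1. **binding** — ChIP of FLAG-tagged GlnR hybridised against total DNA on a
   whole-genome tiling array, giving per-probe IP/total ratio tracks;
2. **response** — replicated expression profiles of the wild type across
   the time course;
3. **dependence** — the same profiles in a `glnR` deletion strain.

Each evidence type has its own module; `classify_regulon()` joins them into
the four regulon categories (i bound + responsive + dependent, ii
responsive + dependent but unbound, iii responsive but independent, iv
bound but non-responsive).

# Peak calling on ratio tracks

The peak rule is deliberately the simple thresholding rule used in
two-colour tiling ChIP-chip studies, not a model-based caller: a probe is
high when its ratio exceeds the track mean by more than `k_sd` standard
deviations, and a peak is a maximal run of at least `min_run` consecutive
high probes.

Parameters (all in `peak_params()`):

| parameter | default | meaning |
|---|---|---|
| `k_sd` | 2.5 | threshold multiplier over the per-track mean |
| `min_run` | 2 probes | minimum run of consecutive high probes |
| `min_replicates` | 2 | distinct replicates that must support a region |
| `max_probe_gap_bp` | 2 × median spacing | largest genomic gap still "consecutive" |
| `use_log_ratio` | `FALSE` | compute mean/sd on log2 ratios instead |

Design choices that the rule itself leaves open, and how this package
resolves them:

* **Mean and sd are computed per track** (per replicate, per timepoint),
  not pooled across experiments. Each hybridisation has its own scale and
  noise; pooling would let a noisy array dilute the threshold of a clean
  one. An externally supplied `threshold` argument supports pooled or
  otherwise precomputed cutoffs.
* **Sample (n − 1) standard deviation.** At tens of thousands of probes the
  difference from the population estimator is far below any other source of
  uncertainty.
* **Linear ratios by default.** The thresholding rule is stated on ratios;
  `use_log_ratio = TRUE` is offered because array noise is multiplicative,
  and the simulator's noise model (log-normal) makes the log scale slightly
  better calibrated — but the default reproduces the stated rule.
* **"Consecutive" requires bounded genomic gaps.** Tiling designs have
  coverage holes; without the gap bound, two high probes flanking a large
  hole would merge into one spurious peak.
* **Cross-replicate merging is single-linkage on ≥ 1 bp overlap**, and the
  reported region is the union of its member peaks. Any merged cluster
  overlapping a control peak (empty-vector IP) at any timepoint is moved to
  a diagnostics list, never silently dropped.
* **Target assignment** takes, per side of a region, the *immediately*
  adjacent gene (nearest start at/after the region on the right, nearest
  end at/before it on the left) and accepts it only if it points away from
  the region, i.e. the region is promoter-proximal upstream of it. A
  divergent pair therefore yields two targets, a tandem context one, a
  convergent context none (counted and messaged). An unbounded
  nearest-downstream search would instead assign distant genes across
  intervening ORFs, which is not what "the gene immediately downstream of a
  binding site" means.

# Expression filtering and dependence

Expression lives in a `SummarizedExperiment` of log2 intensities with
`strain`, `timepoint` and `replicate` column annotations. Replicates are
summarised by the mean of log2 values before fold computation; per-gene
median centring (`median_center()`) is available and provably does not
change fold changes, which depend only on within-gene differences.

* **Fold induction** is T30 over T0; **fold repression** is T30 over T45 —
  expression rises upon starvation and falls again after ammonium
  re-addition, so both are > 1 for a canonical GlnR target.
* The **dual response filter** requires both folds > θ (default 2).
* A gene is **dependent** when it passes the dual filter in the wild type
  (θ_wt) and fails it in the mutant (θ_mutant). "Non-responsive in the
  mutant" has no unique numerical definition; operationalising it as
  *failing either arm of the dual filter at θ = 2* is symmetric with the
  wild-type criterion and exposed as a knob (`theta_mutant`) so stricter
  or looser readings can be audited — both per-strain calls are returned.
* `two_way_anova_bh()` fits the classical fixed-effects
  `log2 ~ strain * timepoint` model gene by gene and applies
  Benjamini–Hochberg per effect across genes. Genes with zero variance get
  p = 1 by convention, so a flat gene can never be called significant.
  Residual degrees of freedom require replication; the function refuses
  single-level factors.

# The bipartite GlnR box

The box is two 5-bp half-sites separated by a spacer:
GTnAC-n6-GTnAC in strict form. The motif *discovery* step of the original
analysis was an external program (MEME); this package encodes the
discovered consensus and complements it with a PWM trained on the bound
sites, which is the part downstream analysis actually consumes.

* Matching is case-insensitive; IUPAC codes in the *pattern* are expanded,
  ambiguity codes in the *subject* never match (conservative; a window
  containing an N is rejected).
* Both strands are always scanned; reverse-strand hits are reported in
  forward coordinates with the matched text read on the matching strand.
  Because the strict box is its own reverse complement (as a pattern),
  every locus appears once per strand — counts of *loci* deduplicate on
  (start, end).
* The relaxed preset (`a = "KTNAC"`, `b = "GWNAC"`) covers the observed
  half-site variants (e.g. TTnAC a-sites and GAnAC b-sites); the spacer
  range generalises to the widely spaced two-a-site arrangement
  (`spacer_max = 18`).
* `build_pwm()` uses a pseudocount of 0.5 per base per column. Per-column
  information content is 2 − H(column) bits, always in [0, 2]; log-odds
  scores in `pwm_scan()` are taken against a configurable background —
  for a genome at ~70 % GC, pass `base_composition(genome)` rather than
  the uniform default, or GC-rich spacers will score too well.
* Promoter windows are `width` bp (default 250) centred on the region
  midpoint and clipped at replicon ends; clipped windows are shorter and
  counted in a message rather than padded, so PWM scores remain honest.

# The simulator

`simulate_study()` generates, under one seed: a GC-rich (70 %) 1 Mb
replicon with 300 non-overlapping genes of mixed orientation; a 60-mer
probe grid at 180 bp spacing (~5,500 probes, the genome-scaled analogue of
a 44,000-probe array over an 8 Mb chromosome); 20 planted binding sites in
wide intergenic gaps, each with a concrete box instance embedded in the
sequence; 2 IP replicates plus one empty-vector control per timepoint; and
a 3-replicate expression design over WT and glnR strains.

The signal model is deliberately minimal: expected ratio
`1 + (fold − 1) · w(d)` with `w` a triangular kernel of 500 bp half-width —
the centre of the 300–1000 bp sonication fragment range — multiplied by
log-normal noise with sd(log2) = 0.25. Planted sites carry no enrichment at
T0 except a designated persistent (glnA-like) site, are fully enriched at
T30, and stay enriched at T45 (binding is not reversed by ammonium
re-addition, even though transcription is). Artefact sites are enriched in
IP *and* control tracks, exercising the control-subtraction path. Planted
expression effects draw induction folds from 4–76.4 and repression folds
from 4–15, the range anchored at the strongest observed target
(ammonium-transporter operon scale); noise is i.i.d. Gaussian with
sd(log2) = 0.25.

What the simulator does **not** emulate: probe sequence affinity and dye
bias, spatial array artefacts, autocorrelated noise, operon structure
(genes respond independently), mRNA-stability carry-over after ammonium
re-addition, and genome-scale gene density. Passing the recovery tests
therefore shows the *logic* of the pipeline is correct under the stated
noise model, not that the thresholds are optimal for any particular real
array platform.

Determinism: each `simulate_*` stage seeds from the scenario seed plus a
fixed stage offset, so stages are individually reproducible and a full
study is byte-identical on re-run (asserted in the tests by checksumming
written bundles).

# Numerical conventions and edge cases

* **Coordinates.** Internally everything is a `GRanges`, i.e. 1-based
  closed intervals — the native convention of the host interval stack, and
  the one its overlap semantics assume. Formats keep their own dialects at
  I/O: GFF3 1-based inclusive, bedGraph/BED 0-based half-open (handled by
  rtracklayer).
* Non-finite or non-positive probe ratios are dropped at load with a
  counted message; a track must keep ≥ 2 probes to have a threshold.
* Overlapping or nested genes are unioned before taking the intergenic
  complement, so they cannot create zero-width or spurious regions.
* `top_table()` breaks fold-induction ties by lexical gene id, making
  reports stable across platforms.
* Circular replicons are treated as linear; no origin-spanning region is
  modelled or expected.
* `classify_regulon()` keeps bound genes that lack expression data,
  flagging them `no_expression_data` (they classify as iv); genes
  responsive in neither strain stay `none`, distinct from category iii.

# Problem sizes in the shipped tests

The test-suite simulations are sized to make every property check sharp but
cheap: most module tests use a 200 kb / 60-gene / 5-site scenario, the
recovery checks use the full default scenario (1 Mb, 300 genes, 20 sites,
260 expression genes), oracle-equivalence checks run 200 random 500-probe
tracks and 100 random 5 kb sequences against brute-force enumerators, and
the null false-discovery check uses 1,000 flat genes. At these sizes the
planted effects (≥ 4-fold enrichment, ≥ 4-fold expression changes at
sd(log2) = 0.25) are recovered exactly; the margins are large by design,
because the tests assert recovery *exactly*, not approximately.

# Known limitations

* The peak rule is a reproduction of a thresholding heuristic; it has no
  error model, and `k_sd` trades sensitivity against specificity in a way
  that depends on the fraction of the genome that is bound (bound probes
  inflate the global mean and sd).
* Fold-change filters on low-expressed genes are noisy; the ANOVA path is
  provided but the headline dependence call follows the fold-change
  definition.
* The 27/9 split of regions with/without consensus sites among the
  transcribed binding regions reflects the published annotation; the
  discovery parameters behind it are not re-derived here.
* Dependence requires complete wild-type *and* mutant time courses; there
  is no imputation.
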