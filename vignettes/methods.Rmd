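---
title: "Inferring gene dosage sensitivity from conserved miRNA targeting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene dosage sensitivity from conserved miRNA targeting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirdosage)
```

## The scientific problem

Genes differ in how much their fitness depends on precise expression
dosage. On the mammalian X and avian Z chromosomes this mattered
historically: when Y- and W-linked homologs decayed, dosage-sensitive
genes either kept their sex-specific homolog (X-Y and Z-W pairs), or —
in mammals — acquired X inactivation after compensatory upregulation,
while insensitive genes simply continued to escape. A readout of dosage
sensitivity that predates the sex chromosomes themselves is the extent of
microRNA (miRNA) targeting of a gene's 3′ UTR: miRNAs tune dosage
downward, so genes under pressure to avoid overexpression accumulate and
retain target sites. `mirdosage` implements that readout end to end:

1. scan 3′ UTRs for canonical miRNA seed-match sites,
2. call sites conserved between species pairs from per-gene alignments,
3. compare each gene's conserved-site count to a shuffled-seed null,
4. segment UTRs into regions of homogeneous background conservation and
   score sites relative to their region,
5. compare gene classes statistically, including copy-number strata,
   bootstrap resampling, and a multinomial class model with AIC-based
   predictor ablation,
6. generate synthetic inputs with known ground truth so that every step
   is testable without external downloads.

## Site grammar

A miRNA family is identified by its 7-nt seed (mature miRNA positions
2–8). On the UTR sense strand the three canonical site types are exact
matches of:

* **7mer-m8** — the reverse complement of the full seed;
* **8mer** — the 7mer-m8 followed by an adenine (the "A1 anchor"
  opposite miRNA position 1);
* **7mer-A1** — complementarity to miRNA positions 2–7 only, again
  followed by the A1 anchor.

Only these three types are scanned: they are the types that carry
conservation scores in published interaction tables; 6mer and
non-canonical sites are out of scope. Coordinates are 0-based and
half-open on the ungapped UTR, which keeps the arithmetic of mapping into
alignment columns unambiguous. Overlapping candidate matches of one
family are resolved by the site-strength hierarchy 8mer > 7mer-m8 >
7mer-A1, ties by smaller start; `N` or any other ambiguity code never
matches.

```{r grammar}
fam <- mirna_family("let-7", "GAGGUAG")
site_patterns(fam)
scan_utr("GGCUACCUCAGG", fam)
```

## Conservation calling

Sites are scanned on the ungapped reference row of a per-gene multiple
alignment and mapped into alignment columns; columns where the reference
is gapped (insertions in other species) fall inside the mapped span. A
site is **conserved** for a species pair when both rows are gap-free and
character-identical over every column of the span — the strictest
reading of perfect identity, including the A1 anchor where it is part of
the site type. The pair need not include the reference: scanning human
UTRs and testing chicken–opossum identity reconstructs the ancestral
state without using human conservation at all, which is how
ancestral-versus-derived questions are separated from lineage-specific
site loss.

## The shuffled-seed background null

A raw conserved-site count confounds targeting with the UTR's overall
conservation. The null model re-scans the same UTR with
composition-preserving permutations of every family seed — the same
grammar, the same overlap resolution, the same conservation call — and
summarizes `n_shuffles` replicate counts by their mean and standard
deviation. Per gene this yields an expectation, a z-score
(undefined when the replicate SD is zero), and the background-adjusted
excess (observed − expected) used in class comparisons. Shuffles that
collide with the seed itself or with any real seed in the family set are
rejected; seeds admitting no valid shuffle (homopolymers, or compositions
whose few permutations are all real seeds) are dropped from both the
observed and the null count. Composition preservation is the minimal
confounder control implied by seed shuffling; the default of 50 shuffles
per family keeps the expectation's Monte-Carlo error well below the
between-gene spread. Global permutations are used rather than
dinucleotide-preserving ones; both the shuffle count and this choice are
exposed as configuration.

## Within-UTR conservation segmentation

Background conservation is not uniform along a UTR; a site inside a
hyper-conserved block looks conserved for free. The per-position 0/1
pair-identity signal is therefore segmented into regions of homogeneous
conservation by minimizing the within-segment sum of squared deviations
from segment means plus a fixed penalty per breakpoint (default
`log(n)`, a BIC-like penalty; minimum segment length 50 nt — about the
scale over which UTR conservation is locally coherent). The search is an
exact O(n²) optimal-partitioning dynamic program rather than a greedy
binary segmentation: greedy splitting can miss the penalized optimum when
two nearby changes mask each other, and the exact program is cheap at UTR
lengths. A site's regionally normalized score is
I(conserved) − segment background level, with the segment chosen by the
site midpoint and a whole-UTR fallback when no segmentation is supplied.

## Statistical layer

* **Distribution tests.** Interaction-level score comparisons use the
  two-sided Kolmogorov–Smirnov test (exact when
  `n_x · n_y ≤ 10000` and tie-free); gene-level comparisons of per-gene
  means use the two-sided Wilcoxon rank-sum test. For
  `n_x + n_y ≤ 12` the rank-sum p-value is computed by exact
  enumeration of all group assignments with midranks, so ties are exact;
  larger samples use the tie- and continuity-corrected normal
  approximation. 2×2 analyses use Fisher's exact test, with an all-zero
  table defined as p = 1. Raw two-sided p-values are reported per
  comparison; no multiplicity correction is applied by default.
* **CNV stratification.** Duplicated versus nonduplicated genes are
  compared within each deletion stratum and vice versa, so each
  dosage-change axis is controlled for the other.
* **Resampling.** Class differences in mean gene-level score are
  bootstrapped by resampling genes with replacement within class
  (percentile 95% CI), guarding against a few genes driving a class
  difference.
* **Class model.** Multinomial logistic regression (via `nnet::multinom`,
  reference class = first factor level, i.e. alphabetically first) models
  class membership from haploinsufficiency probability, expression
  breadth, dN/dS and mean conservation score; predictor ablation refits
  on identical rows and reports the AIC change. Possible separation is
  flagged when coefficients diverge; rank-deficient designs are rejected
  naming the collinear columns.

A note on test calibration checks: rank-based and exact conditional
tests have discrete null distributions, so their attainable level at
α = 0.05 depends on the group sizes. The type-I-error checks in the test
suite use sizes at which the statistic's support is fine — near-coprime
group sizes for KS (equal sizes make D's support coarse and the test
conservative) and large margins for Fisher — so that the nominal level
is meaningful.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with one latent quantity — per-gene dosage sensitivity — driving every
coupling:

* **Alignments.** A reference UTR is drawn uniformly over {A,C,G,U}
  (default length 1500–2500 nt, the scale of typical mammalian 3′ UTRs).
  Each partner species row is generated independently position by
  position, identical to the reference with a per-segment probability
  (segments of mean length 300 nt, identity levels uniform on
  0.80–0.95, giving within-UTR conservation heterogeneity). There is no
  explicit phylogeny and no indels: the analysis consumes only pairwise
  identity, so an identity-versus-reference model exercises every code
  path while keeping ground truth exact. Planted sites are copied intact
  to a partner with the class's retention probability; a non-retained
  site receives exactly one substitution inside the span — the minimal
  perturbation defeating perfect identity. Flanking bases of planted
  7mers are guarded so a chance neighbour cannot extend them into a
  stronger overlapping type, keeping the planted truth recoverable by
  the scanner.
* **Classes.** Gene classes with a configured retention probability
  (e.g. X-Y pair 0.8, X-inactivated 0.5, X escape 0.2) get that value,
  jittered by N(0, 0.05), as their latent sensitivity; classes without
  one (autosomal genes) draw sensitivity from Beta(2, 2), a continuum.
* **Covariates** shift with sensitivity (higher haploinsufficiency
  probability and expression breadth, lower dN/dS), with effect sizes
  set so that class differences are detectable at a few hundred genes
  without being trivial.
* **CNV status.** Duplication probability decreases with sensitivity
  through a logit link (default slope 3; deletions use a weaker slope of
  1.5, matching the expectation that miRNA targeting is most informative
  about sensitivity to dosage increases).
* **Expression ratios.** For Z-linked genes without a W homolog, the
  magnitude of the log2 male/female ratio decreases with the gene score
  rank — from 0.5 (an uncompensated single Z dose) down to 0.1
  (near-complete compensation) at full coupling; genes with a surviving
  W homolog are centred at 0 per the two-copy expectation.

What the generator does *not* emulate: realistic substitution processes,
indel evolution, UTR composition bias, phylogenetic correlation among
partner species, and shared miRNA family evolution. Passing tests
therefore demonstrate the correctness and statistical calibration of the
machinery, not the field realism of any particular effect size.

## Numerical and design choices

* The per-gene background statistic is a z-score (and the
  observed − expected excess) against the shuffle distribution — a
  scale-free summary across UTR lengths; the z is left undefined rather
  than imputed when the shuffle SD is zero.
* Genes without any scored interaction are excluded from score-based
  comparisons, not imputed at zero.
* CNV thresholds default to "any event" (≥ 1), the binary
  exhibiting-or-lacking framing; thresholds are configuration.
* Variably escaping XCI genes are not a modelled class; the annotation
  reader accepts only the six canonical labels and rejects others.
* Pipeline stages communicate through files with `# key=value` metadata
  headers (configuration hash and seeds, never timestamps), so a rerun
  with identical configuration is byte-identical, and any stage's input
  can be replaced by real data in the same dialect.
* Multinomial optimization relies on `nnet::multinom` with a tightened
  convergence tolerance; the AIC identity (2k − 2 logL) and nested-model
  likelihood ordering are asserted in tests rather than re-deriving the
  optimizer.

## Problem sizes used in the checks

The test suite and the acceptance script size their simulations to be
informative yet quick: null calibration uses 500 (tests) or 300
(acceptance script) site-free genes with the default 50-family set and
50 shuffles; the three-class heterogeneity experiment uses 100 genes per
class, 10 planted sites per gene, 25 families, 25 shuffles and 0.8–1.2 kb
UTRs per replicate run; changepoint recovery uses 200 replicates of a
400-nt signal with a 0.9 → 0.2 step; coefficient recovery uses n = 600
genes over 20 replicates. At these sizes the Monte-Carlo error of each
check sits well inside the asserted bands.

## Known limitations

* Conservation is binary perfect identity; branch-length weighting and
  probabilistic conservation scoring are consumed as input when
  available, never recomputed.
* The exact segmentation program is quadratic in UTR length; for
  100-kb-scale sequences a pruned search would be preferable.
* The shuffle null conditions on the alignment; it does not model
  alignment uncertainty.
* Interaction-level tests treat each gene–miRNA score as one
  observation, so interactions of one gene are not independent; the
  gene-level tests are the conservative companion and both are always
  reported.
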