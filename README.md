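# mirdosage

Infer gene dosage sensitivity from the conservation of microRNA target
sites in 3′ UTRs, and test whether such sensitivities distinguish classes
of sex-linked genes — X-Y / Z-W pairs, X-inactivated genes, X escape
genes, dosage-compensated Z-linked genes — as well as autosomal genes
stratified by copy-number variation.

## Who this is for

Comparative genomicists and molecular evolution researchers who want a
tested, reproducible implementation of the ancestral miRNA-targeting
readout of dosage sensitivity: site scanning, cross-species
perfect-identity conservation calls, a shuffled-seed background null,
within-UTR conservation segmentation, and the class-comparison
statistics built on top — plus a synthetic-data generator with known
ground truth so every stage can be validated offline.

## The method in brief

For a miRNA family with 7-nt seed *s* (mature positions 2–8), the
canonical UTR sites are exact matches of the reverse complement of *s*
(7mer-m8), that pattern followed by an A (8mer), and complementarity to
positions 2–7 followed by an A (7mer-A1). For a gene *g* and a species
pair, the observed statistic is the number of sites on the reference UTR
whose alignment columns are gap-free and identical in both species. Its
background expectation is estimated by re-scanning with
composition-preserving permutations of every seed:

    z_g = (obs_g − mean(null_g)) / sd(null_g),
    excess_g = obs_g − mean(null_g)

Class structure is then assessed with two-sided KS tests (interaction
level), Wilcoxon rank-sum tests (gene level, exact by enumeration for
small samples), Fisher's exact test, bootstrap gene resampling, and a
multinomial logistic model of class membership

    P(class_g = k) ∝ exp(β₀ₖ + β₁ₖ·pHI + β₂ₖ·breadth + β₃ₖ·dN/dS + β₄ₖ·score)

whose predictors are ablated one at a time and compared by AIC
(2k − 2 logL). Within-UTR conservation heterogeneity is handled by an
exact penalized changepoint program over the per-position identity
signal, scoring each site against its region's background level.

## Worked example

```r
library(mirdosage)

# scan a UTR for let-7 family sites
fam <- mirna_family("let-7", "GAGGUAG")
scan_utr("GGCUACCUCAGG", fam)
#>   gene_id family_id site_type start end
#> 1    <NA>     let-7      8mer     2  10

# simulate a three-class study and run the full pipeline
cfg <- simulation_config(
  rng_seed = 42L,
  n_genes_per_class = c(XY_pair = 30L, X_inactivated = 30L, X_escape = 30L),
  site_retention_prob = c(XY_pair = 0.8, X_inactivated = 0.5, X_escape = 0.2),
  utr_length_range = c(800L, 1200L), n_families = 20L, sites_per_gene = 10L)
run_pipeline(cfg, "run1", n_shuffles = 25L, n_boot = 500L)

bg  <- read_tsv_meta("run1/background.tsv")
med <- tapply(bg$n_conserved - bg$expected,
              read_gene_annotations("run1/annotations.tsv")$class, median)
round(med, 2)
#>      X_escape X_inactivated       XY_pair
#>          1.44          4.54          8.32

cmp <- read_tsv_meta("run1/comparisons.tsv")
subset(cmp, analysis == "ancestral_excess", c(group_a, group_b, p_value))
#>         group_a       group_b      p_value
#> 7       XY_pair X_inactivated 3.634818e-08
#> 8       XY_pair      X_escape 4.496005e-11
#> 9 X_inactivated      X_escape 7.305627e-07
```

The class medians of the background-adjusted conserved-site counts
(`n_conserved − expected`) recover the planted retention ordering
0.8 > 0.5 > 0.2 at roughly 10 sites per gene, and all pairwise rank-sum
tests reject decisively. `run1/report.md` summarizes every comparison,
the model ablation, the seeds and the configuration hash.

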