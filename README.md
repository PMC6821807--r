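# fourc

One-viewpoint chromosome conformation capture (4C-seq) asks how often a
fixed genomic position — a promoter, or a candidate enhancer — touches every
other locus, and whether that contact landscape changes between genotypes.
The motivating use case is regulatory genetics of the cardiac sodium channel
locus: a heterozygous deletion of a downstream enhancer cluster that reduces
promoter–enhancer contacts, silences the deleted allele, and halves total
*Scn5a* output. `fourc` implements the complete analysis for that kind of
experiment, plus seeded synthetic-data generators so every stage runs and is
tested without any external download. It is written for genomicists who have
(or simulate) viewpoint-tagged 4C reads and a set of candidate positions to
test.

## What it computes

**Frag-end reduced genome.** The genome is digested in silico at every
primary restriction site (DpnII, `GATC`); the sequences directly flanking
each cut site ("frag-ends", default 36 bp read inward) form the mapping
units. Frag-ends whose sequence is not unique genome-wide are flagged and
their reads discarded; fragments without a secondary site (Csp6I, `GTAC`)
are flagged blind. Coordinates are 0-based half-open (BED-native).

**Contact profiles.** A read is assigned to frag-end *f* iff it starts with
the viewpoint reading primer and the following bases exactly match *f*'s
sequence or its reverse complement. Per replicate, the highest-coverage
frag-end (the viewpoint's self-ligation signal) is removed, counts are
scaled by *s* = 10⁶ / Σ cis so intrachromosomal coverage sums to exactly one
million, and the displayed profile is the running mean over 21 consecutive
frag-ends.

**Differential contacts.** Anchors of 10 Kb (half-width *hw* = 5,000 bp,
interval [center − *hw*, center + *hw*)) are placed at pre-specified
positions; normalized (unsmoothed) coverage is summed over member frag-ends
per replicate; each anchor is tested with the unpaired Student's t test
(pooled variance, df = *n*₁ + *n*₂ − 2, two-sided p).

**Allelic expression.** RT-qPCR-style quantities are normalized to the
geometric mean of reference genes, fold changes are ratios of group means,
and a two-allele activity model (*a*₁, *a*₂) predicts the expression
consequence of an enhancer deletion: reduction = 100 × (1 − (*a*₁ + *a*₂)/2)
percent; for a heterozygote with a fully silenced allele, (1, 0), that is a
50% reduction with zero transcript from the silenced allele — monoallelic
expression.

**Synthetic data.** Contact weights decay as ε + (1 + d/s)^(−α) with
distance d from the viewpoint; genotype-specific multipliers act on effect
regions; reads are multinomial draws expanded to primer-tagged sequences.
Expression cohorts add log-normal measurement noise and per-sample loading
factors. Everything is deterministic under one seed.

## Worked example

```r
library(fourc)

# default scenario: 2 genotypes x 3 replicates, 20,000 cis + 2,000 trans
# reads each; contacts over chr1:585,000-595,000 halved in the "het" group
res <- run_scenario(sim_config(seed = 101))
res$results[, c("anchor", "n_fragends", "mean_a", "mean_b",
                "ratio_b_over_a", "t_stat", "p_value")]
```

```
        anchor n_fragends mean_a mean_b ratio_b_over_a   t_stat   p_value
  neutral_300k         66   8344   8778         1.0520 -1.61121 1.824e-01
  neutral_400k         36   9137   8681         0.9501  0.48208 6.549e-01
 enhancer_like         50  14484   7052         0.4869 19.70434 3.913e-05
  neutral_700k         56   8427   8448         1.0025 -0.04399 9.670e-01
  neutral_800k         56   6074   5605         0.9228  1.09953 3.333e-01
```

The perturbed anchor is recovered at a contact ratio of 0.49 — the expected
0.5 of a heterozygous deletion — with p = 3.9e-05, while the four neutral
anchors stay near ratio 1 with non-significant p. `mean_a`/`mean_b` are
summed normalized coverages (units of reads per million intrachromosomal),
averaged over the three replicates of each group.

The expression side of the same genetics:

```r
monoallelic_prediction(c(1, 0))
#> allele model: 50% reduction vs wildtype; allele fractions 1 / 0
```

A step-by-step narrative of the same analysis — simulation, frag-end
library, per-replicate profiles, anchor tests, expression — lives in the
numbered scripts under `analysis/` (run them in order from the repository
root); methods and design rationale are in
`vignettes/contact-profile-methods.Rmd`.

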