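---
title: "Methods: 4C contact profiles, anchor tests and the two-allele expression model"
author: "fourc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 4C contact profiles, anchor tests and the two-allele expression model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fourc)
```

# The measurement and the reduced genome

One-viewpoint chromosome conformation capture (4C-seq) measures how often a
fixed genomic position — the viewpoint, typically a promoter or a candidate
regulatory element — is in physical contact with every other locus.
Cross-linked chromatin is digested with a frequent-cutting primary enzyme
(DpnII, `GATC`), ligated, digested again with a secondary enzyme (Csp6I,
`GTAC`), re-ligated into small circles, and amplified by inverse PCR with a
reading primer that ends at the viewpoint's primary restriction site. Each
sequencing read therefore starts with the reading primer and continues into
the captured partner fragment.

Because every captured sequence begins at a primary restriction site, reads
need only be mapped against the sequences *directly flanking* primary sites —
the **frag-ends**. `build_fragend_library()` constructs this reduced genome:
the genome is digested in silico at every occurrence of the primary motif
(cuts at motif start; overlapping occurrences allowed; motifs never match
across `N`), and for each fragment boundary abutting a cut site the first
`extract_len` bases read inward are extracted, truncating at the opposite
fragment boundary. Coordinates are 0-based and half-open throughout, so BED
output needs no conversion.

Three annotations drive downstream filtering:

* **Uniqueness.** A frag-end is unique iff its sequence occurs exactly once
  among all frag-end sequences (case-insensitive). Non-unique frag-ends are
  kept in the library but reads matching them are discarded — the reduced-
  genome analogue of discarding multi-mapping reads. Sequences containing
  `N` are conservatively marked non-unique, mirroring unmappable regions.
* **Blind fragments.** A fragment with no secondary-motif occurrence cannot
  be shortened by the second digestion. Whether such frag-ends should be
  excluded is not settled usage; they are **retained** by default and the
  flag is exposed, so exclusion is a one-line filter for users who want it.
* **Strand convention.** Frag-end sequences are stored as plus-strand genome
  text read inward. A right-side frag-end is sequenced leftward in reality,
  so read assignment accepts either the stored sequence or its reverse
  complement; storing one canonical representation keeps the library simple.

`extract_len` defaults to 36 bp — a typical trimmed-read length after primer
removal; it is configurable and nothing downstream depends on its exact
value as long as it is long enough to make most frag-ends unique.

# From reads to a contact profile

`assign_reads()` replaces both demultiplexing and alignment with exact
string matching: a read counts toward frag-end $f$ iff it begins with the
viewpoint's reading primer and its next $k$ bases
($k = \min(\text{remaining length}, \texttt{extract\_len})$) equal $f$'s
sequence or its reverse complement. This is an honest substitution at the
scale this package operates on: the reads it quantifies are error-free
synthetic reads, for which exact matching and alignment coincide, and the
frag-end assignment semantics — including the discard of non-unique
frag-ends — are preserved. Reads are tallied into three discard categories
(`no_primer`, `no_match`, `non_unique`) so that
assigned + discarded = input, an invariant the tests enforce. A mismatch
tolerance knob is deliberately absent: tolerant matching without a quality
model would only blur the assignment.

The profile then passes through a small state machine
(`raw → filtered → normalized → smoothed`), with each transition validating
its precondition:

1. **`remove_top_fragend()`** removes the single highest-coverage frag-end —
   in practice the viewpoint's own self-ligation signal, which would
   otherwise dominate the cis total. Ties are broken by lowest genomic
   coordinate, then chromosome name, making the choice deterministic. The
   removal happens *before* normalization so the removed count never enters
   the cis sum.
2. **`normalize_profile()`** multiplies every count (cis and trans) by
   $s = 10^6 / \sum_{\text{cis}} c_i$, so intrachromosomal coverage sums to
   exactly one million. Cis means the viewpoint's chromosome. An all-zero or
   cis-zero profile is an error, not a silent zero division.
3. **`running_mean()`** smooths per chromosome with a centred window of 21
   consecutive frag-ends — the displayed contact profile. Within 10
   positions of a chromosome edge the window shrinks symmetrically to the
   largest centred window that fits; mirrored or zero-padded edges were
   rejected because both fabricate signal where there is none. Smoothing is
   applied uniformly per chromosome (trans chromosomes included when
   present), but anchors never read smoothed values. Frag-ends with zero
   coverage are retained: dropping them would make the window width
   data-dependent.

# Anchor tests

`build_anchors()` places a fixed-width window (default half-width 5,000 bp,
i.e. a 10 Kb anchor) around each pre-specified test position. Membership is
by frag-end boundary position in the half-open interval
$[\text{center} - hw, \text{center} + hw)$; the half-open choice and the use
of the frag-end position (rather than fragment midpoints) are the
conventions this package fixes where usage varies — they make membership
unambiguous at shared boundaries and independent of fragment length.
Overlapping anchors simply share frag-ends; empty anchors are kept and
flagged.

`anchor_sums()` sums **normalized, unsmoothed** coverage over member
frag-ends per replicate — smoothing is for display, and summing smoothed
values would double-count neighbours. `anchor_ttest()` compares the two
genotype groups with the unpaired Student's t test (pooled variance,
$\mathrm{df} = n_A + n_B - 2$, two-sided p). Pooled rather than Welch was
chosen to match the stated test; Welch is available behind a flag.
Degenerate inputs are flagged explicitly: zero pooled variance with equal
means gives $t = 0, p = 1$ (`degenerate`), with unequal means
$t = \pm\infty, p = 0$ (`infinite_t`). Raw p-values are reported — the test
is run on a handful of pre-specified anchors, not genome-wide — and a
Benjamini–Hochberg column (`p_bh`) is appended, clearly labelled as a
convenience.

One compositional caveat belongs here: because every profile is rescaled to
a fixed cis total, halving the contacts in one region inflates all other
cis values by the lost fraction. With the default scenario the effect
region carries roughly 1.5% of cis coverage, so the inflation is ~0.7% —
far below replicate noise — but for a large perturbed fraction the neutral
anchors would shift visibly. This is a property of read-depth-normalized
4C data generally, not of this implementation.

# The two-allele expression model

Expression quantities enter as relative start concentrations (as produced
by LinRegPCR-style analysis of qPCR amplification curves; Cq/efficiency
modelling is out of scope). `normalize_expression()` divides each gene by
the per-sample geometric mean of the reference genes (defaults in the
simulated cohort: cTnI and Hprt), which cancels any uniform per-sample
loading factor exactly. `fold_change()` is the ratio of arithmetic group
means of normalized quantities, matching mean-±-SEM summaries, and
`expression_test()` reuses the same pooled-t kernel as the anchor tests —
one statistical kernel, tested once.

`monoallelic_prediction()` formalizes the genetics: total transcript output
is the sum of two per-allele activities $(a_1, a_2)$ with wildtype
$\equiv (1, 1)$. The predicted reduction versus wildtype is
$100 \times (1 - (a_1 + a_2)/2)$ percent, and the silenced allele's share of
the cDNA is $a_{\text{silenced}}/(a_1 + a_2)$. A heterozygote whose deleted
allele is fully silenced — activities $(1, 0)$ — therefore shows exactly a
50% reduction in total output and a diagnostic-variant allele fraction of 0:
monoallelic expression. The model is linear in each activity, so partial
enhancer losses map to intermediate activities; no default partial activity
is asserted because the on/off model cannot derive one.

# What the generator emulates — and what it does not

`sim_config()` / `simulate_genome()` / `simulate_4c_reads()` /
`simulate_expression()` generate data with the statistical structure the
analysis assumes, sized to the replicate design the pipeline targets: two
genotypes × three replicates, one viewpoint, 20,000 cis + 2,000 trans reads
per replicate.

* **Genome.** Two 1 Mb chromosomes of random sequence at GC 0.45. Chance
  primary-motif occurrences are scrubbed and sites are injected with
  exponentially distributed gaps so the mean GATC spacing is a controlled
  400 bp (dense enough for ~50 frag-ends per 10 Kb anchor); secondary
  (GTAC) sites are left to chance, giving a realistic minority of blind
  fragments. Self-overlap-free motifs like GATC make injection exact.
* **Contacts.** Cis sampling weight at distance $d$ from the viewpoint is
  $w(d) = \epsilon + (1 + d/s)^{-\alpha}$ with scale $s = 20$ kb, exponent
  $\alpha = 1$ and floor $\epsilon = 10^{-4}$; trans frag-ends sit at
  $\epsilon$. This is a standard phenomenological distance-decay shape —
  chosen, not fitted, since the pipeline estimates nothing from it. A
  genotype-specific effect region multiplies weights inside its interval
  (default: ×0.5 over a 10 Kb region 90 Kb downstream of the viewpoint in
  the mutant — a heterozygous enhancer deletion's contact signature, since
  pooling both alleles halves that region's contact frequency).
* **Reads.** Each replicate is one multinomial draw of the configured total
  over frag-end weights, expanded to primer + frag-end-sequence reads
  (reverse-complemented for right-side frag-ends). There is **no** PCR
  duplicate structure, no ligation-frequency model, no sequencing error and
  no biological between-replicate overdispersion. Consequently the
  replicate noise is pure sampling noise: the type-I calibration and power
  the tests demonstrate apply to the statistical machinery, not to real 4C
  libraries, whose replicate variance is larger and whose p-values would be
  correspondingly weaker. The generator is a test harness for the pipeline's
  contracts, not a forward model of the assay chemistry.
* **Expression.** Quantity = baseline × genotype multiplier × log-normal
  measurement noise (CV 0.15) × per-sample log-normal loading factor
  (CV 0.2), with reference genes pinned at multiplier 1. The loading factor
  cancels exactly under geomean normalization; the residual ~1% bias from
  taking ratios of noisy log-normals is well inside the tolerances used.

All generators are deterministic under the configuration seed, with
independent sub-streams per task (genome, reads per genotype, expression)
derived by hashing, so regenerating one component never perturbs another.

# Numerical and testing choices

* Problem sizes: unit tests run on 4–8 Kb toy genomes; contract-level tests
  use the full default scenario (2 × 1 Mb, 22,000 reads × 6 replicates),
  240 null Monte-Carlo repetitions for the type-I check and 50 repetitions
  for effect recovery — sizes at which the binomial 99% acceptance band
  around the nominal 0.05 rate is tight enough to be informative while the
  whole suite runs in about a minute.
* The recovered contact ratio at the perturbed anchor is assessed as the
  mean over the 50 repetitions (single-repetition ratios at this read depth
  scatter with ~6% CV around 0.5, so a per-repetition bound would test the
  noise, not the recovery).
* Normalization is validated to 1 ppm relative; smoothing against a naive
  sliding-window oracle to 1e-12; the t kernel against an independently
  coded closed form to |Δt| < 1e-10 and against `stats::t.test(var.equal =
  TRUE)`.
* Byte-level determinism of the end-to-end run is tested by md5 on the
  output tables; all numbers are written with fixed 15-digit formatting to
  keep the files locale- and precision-stable.

# Limitations

* Exact-match assignment cannot process real, error-containing FASTQ files;
  plugging in an aligner upstream and importing per-frag-end counts via
  `profile_from_counts()` is the supported route for real data.
* The pipeline quantifies one viewpoint per run; multi-viewpoint pools are
  handled only through the primer match.
* No genome-wide interaction calling: anchors must be pre-specified, which
  is the intended use (hypothesis-driven tests at candidate regulatory
  elements) and avoids the multiple-testing machinery a genome-wide scan
  would require.
* The two-allele model treats alleles as independent transcriptional units;
  trans-compensation or dosage feedback would break the factor-of-two
  arithmetic, and the model makes no claim about them.
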