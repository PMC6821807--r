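#!/usr/bin/env Rscript
# Materialize the default synthetic scenario: a two-chromosome genome with
# DpnII sites every ~400 bp, a 4C viewpoint mid-chr1, three wildtype and
# three heterozygous-deletion replicates of 20,000 cis + 2,000 trans reads,
# with contacts over the enhancer-like region [585k, 595k) halved in the
# mutant, plus a matched RT-qPCR-style expression cohort.

suppressPackageStartupMessages(library(fourc))

cfg <- sim_config(seed = 101)
out <- "results/sim"
sc <- write_scenario(cfg, out)

cat("Simulated scenario written to", out, "\n")
cat("  genome:", length(sc$genome), "chromosomes x",
    format(nchar(sc$genome[[1]]), big.mark = ","), "bp\n")
cat("  frag-ends:", nrow(sc$library),
    sprintf("(%d unique, %d blind)\n", sum(sc$library$is_unique),
            sum(sc$library$is_blind)))
cat("  read sets:", length(sc$paths$reads), "replicates x",
    format(cfg$n_reads_cis + cfg$n_reads_trans, big.mark = ","), "reads\n")
cat("  effect region:", cfg$effect_regions$chrom[1],
    sprintf("[%d, %d) multiplier %.2f in genotype %s\n",
            cfg$effect_regions$start[1], cfg$effect_regions$end[1],
            cfg$effect_regions$multiplier[1], cfg$effect_regions$genotype[1]))
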