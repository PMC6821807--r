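# Seeded generators for synthetic genomes, 4C read sets and expression
# cohorts with the statistical structure the analysis assumes: contact
# frequency decaying with genomic distance from the viewpoint, a uniform
# trans background, genotype-specific effect multipliers over designated
# regions, and log-normal replicate noise for expression.

#' Simulation configuration
#'
#' Collects every parameter of the synthetic 4C and expression generators.
#' The defaults describe the default scenario: two chromosomes of 1 Mb
#' (chr1 carries the viewpoint at its midpoint, chr2 is pure trans
#' background), primary-site spacing averaging 400 bp, two genotypes
#' ("WT", "het") with 3 biological replicates each, 20,000 cis plus 2,000
#' trans reads per replicate, and a single 10 Kb enhancer-like region
#' 90 Kb downstream of the viewpoint whose contact weight is halved in the
#' "het" genotype — the contact signature of a heterozygous enhancer
#' deletion — alongside neutral anchor positions for comparison.
#'
#' The cis contact weight at distance `d` from the viewpoint is
#' `background_floor + (1 + d / decay_scale)^(-decay_exponent)`, a standard
#' phenomenological distance-decay form; trans frag-ends sit at
#' `background_floor`.
#'
#' @param seed Integer seed; all generators are deterministic under it.
#' @param n_chroms,chrom_length Genome shape (chromosomes named
#'   `chr1..chrN`, equal lengths in bp).
#' @param gc_fraction GC content of the random background sequence.
#' @param motif_spacing_mean Mean spacing (bp) between primary-motif
#'   occurrences, achieved by scrubbing chance occurrences and injecting
#'   sites at exponentially distributed gaps.
#' @param vp A [viewpoint()]; default sits mid-chr1 with a 20 bp reading
#'   primer ending in the primary motif, as 4C reading primers do.
#' @param scheme A [restriction_scheme()].
#' @param n_reads_cis,n_reads_trans Expected cis/trans read counts per
#'   replicate; their sum is drawn exactly, split according to the weights.
#' @param decay_scale,decay_exponent,background_floor Contact-decay
#'   parameters (bp / dimensionless / relative weight).
#' @param effect_regions Data.frame `chrom`, `start`, `end`, `genotype`,
#'   `multiplier`: contact weights of frag-ends inside an interval are
#'   multiplied by `multiplier` when simulating that genotype.
#' @param genotypes Genotype labels, first = reference.
#' @param n_replicates Biological replicates per genotype.
#' @param anchor_centers Data.frame `chrom`, `center`, `name` of positions
#'   to test; the default puts one anchor on the effect region and four on
#'   neutral positions.
#' @param halfwidth,window,norm_target Anchor half-width (bp), running-mean
#'   window, and normalization target carried along for the pipeline.
#' @param expression Expression-generator block: `genes` (data.frame
#'   `gene`, `baseline`), `effects` (named list per genotype of named
#'   multiplier vectors), `reference_genes`, `cv` (per-measurement
#'   log-normal coefficient of variation), `sample_scale_cv` (per-sample
#'   loading factor CV), `n_per_genotype`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 1000000L,
                       gc_fraction = 0.45,
                       motif_spacing_mean = 400,
                       vp = viewpoint("vp_promoter", "chr1", 500000L,
                                      reading_primer = "GTCCCAAGGGCACACTGATC"),
                       scheme = restriction_scheme(),
                       n_reads_cis = 20000L,
                       n_reads_trans = 2000L,
                       decay_scale = 20000,
                       decay_exponent = 1,
                       background_floor = 1e-4,
                       effect_regions = data.frame(
                         chrom = "chr1", start = 585000L, end = 595000L,
                         genotype = "het", multiplier = 0.5,
                         name = "enhancer_like"
                       ),
                       genotypes = c("WT", "het"),
                       n_replicates = 3L,
                       anchor_centers = data.frame(
                         chrom = "chr1",
                         center = c(300000L, 400000L, 590000L, 700000L, 800000L),
                         name = c("neutral_300k", "neutral_400k",
                                  "enhancer_like", "neutral_700k",
                                  "neutral_800k")
                       ),
                       halfwidth = 5000L,
                       window = 21L,
                       norm_target = 1e6,
                       expression = list(
                         genes = data.frame(
                           gene = c("Scn5a", "Scn10a", "cTnI", "Hprt"),
                           baseline = c(1.0, 0.6, 5.0, 2.0)
                         ),
                         effects = list(het = c(Scn5a = 0.5)),
                         reference_genes = c("cTnI", "Hprt"),
                         cv = 0.15,
                         sample_scale_cv = 0.2,
                         n_per_genotype = 5L
                       )) {
  stopifnot(decay_exponent > 0, gc_fraction >= 0, gc_fraction <= 1,
            background_floor >= 0, n_replicates >= 1,
            all(effect_regions$multiplier >= 0))
  config <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = as.integer(chrom_length), gc_fraction = gc_fraction,
    motif_spacing_mean = motif_spacing_mean, vp = vp, scheme = scheme,
    n_reads_cis = as.integer(n_reads_cis),
    n_reads_trans = as.integer(n_reads_trans),
    decay_scale = decay_scale, decay_exponent = decay_exponent,
    background_floor = background_floor, effect_regions = effect_regions,
    genotypes = genotypes, n_replicates = as.integer(n_replicates),
    anchor_centers = anchor_centers, halfwidth = as.integer(halfwidth),
    window = as.integer(window), norm_target = norm_target,
    expression = expression
  )
  class(config) <- "sim_config"
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_chroms, " x ", x$chrom_length, " bp, ",
      length(x$genotypes), " genotypes x ", x$n_replicates, " replicates, ",
      x$n_reads_cis, " cis + ", x$n_reads_trans,
      " trans reads/replicate, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# deterministic per-task sub-seed below 2^31, so independent generator calls
# under one master seed do not share streams
subseed <- function(seed, ...) {
  parts <- c(seed, vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }, numeric(1)))
  as.integer(sum(parts * seq_along(parts) * 2654435761) %% 2147483647)
}

#' Simulate a genome with controlled restriction-site density
#'
#' Generates random sequence at the configured GC content, scrubs chance
#' primary-motif occurrences, then injects primary sites at exponentially
#' distributed gaps so that the mean spacing between motif starts equals
#' `motif_spacing_mean`. Secondary-motif occurrences are left to chance, so
#' a realistic minority of fragments is blind. Deterministic under
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return Named character vector of chromosome sequences (`chr1..chrN`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(subseed(config$seed, "genome"))
  motif <- config$scheme$primary
  genome <- vapply(seq_len(config$n_chroms), function(i) {
    simulate_chromosome(config$chrom_length, config$gc_fraction, motif,
                        config$motif_spacing_mean)
  }, character(1))
  names(genome) <- paste0("chr", seq_len(config$n_chroms))
  genome
}

simulate_chromosome <- function(len, gc, motif, spacing_mean) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  v <- sample(names(p), len, replace = TRUE, prob = p)
  seq_str <- paste(v, collapse = "")
  # scrub chance occurrences of the primary motif so the injected sites set
  # the spacing; mutating the second base cannot leave an occurrence behind,
  # but re-scan in case a mutation created a new one upstream
  for (iter in 1:10) {
    occ <- motif_starts(seq_str, motif)
    if (length(occ) == 0L) break
    repl <- sample(setdiff(names(p), substr(motif, 2L, 2L)),
                   length(occ), replace = TRUE)
    for (k in seq_along(occ)) v[occ[k] + 2L] <- repl[k]
    seq_str <- paste(v, collapse = "")
  }
  # inject motif starts with mean spacing `spacing_mean`: consecutive starts
  # are motif_len + Exp(mean = spacing_mean - motif_len) apart
  ml <- nchar(motif)
  n_est <- ceiling(len / spacing_mean * 1.5) + 50L
  gaps <- ml + stats::rexp(n_est, rate = 1 / max(spacing_mean - ml, 1))
  starts <- floor(cumsum(gaps))
  starts <- starts[starts <= len - ml]
  mv <- strsplit(motif, "")[[1]]
  for (s in starts) v[(s + 1L):(s + ml)] <- mv
  paste(v, collapse = "")
}

#' Contact-sampling weights for one genotype
#'
#' One weight per frag-end of `library`: cis frag-ends (the viewpoint's
#' chromosome) get `background_floor + (1 + d / decay_scale)^(-decay_exponent)`
#' with `d` the distance of the frag-end boundary from the viewpoint; trans
#' frag-ends get `background_floor`. Weights of frag-ends inside an effect
#' region whose genotype matches are multiplied by the region's multiplier.
#'
#' @param library A `fragend_library`.
#' @param config A [sim_config()].
#' @param genotype Genotype label to simulate.
#' @return Numeric weight vector aligned with `library` rows.
#' @export
contact_weights <- function(library, config, genotype) {
  vp <- config$vp
  cis <- library$chrom == vp$chrom
  d <- abs(library$pos - vp$position)
  w <- rep(config$background_floor, nrow(library))
  w[cis] <- w[cis] +
    (1 + d[cis] / config$decay_scale)^(-config$decay_exponent)
  er <- config$effect_regions
  if (!is.null(er) && nrow(er) > 0L) {
    for (i in seq_len(nrow(er))) {
      if (er$genotype[i] != genotype) next
      hit <- library$chrom == er$chrom[i] &
        library$pos >= er$start[i] & library$pos < er$end[i]
      w[hit] <- w[hit] * er$multiplier[i]
    }
  }
  if (sum(w) <= 0) stop("zero total contact weight")
  w
}

#' Simulate per-frag-end 4C read counts
#'
#' Draws `n_reads_cis + n_reads_trans` reads per replicate by weighted
#' sampling with replacement over the frag-ends ([contact_weights()]),
#' i.e. one multinomial draw per replicate, so the emitted read count
#' exactly equals the configured total.
#'
#' @param library A `fragend_library`.
#' @param config A [sim_config()].
#' @param genotype Genotype label.
#' @param n_replicates Number of replicates (default `config$n_replicates`).
#' @param seed Seed (default derived from `config$seed` and the genotype).
#' @return Integer matrix, frag-ends x replicates.
#' @export
simulate_4c_counts <- function(library, config, genotype,
                               n_replicates = config$n_replicates,
                               seed = subseed(config$seed, "4c", genotype)) {
  w <- contact_weights(library, config, genotype)
  set.seed(seed)
  total <- config$n_reads_cis + config$n_reads_trans
  counts <- stats::rmultinom(n_replicates, size = total, prob = w)
  colnames(counts) <- paste0(genotype, "_rep", seq_len(n_replicates))
  counts
}

#' Simulate 4C read sets (FASTQ-ready) for one genotype
#'
#' Expands [simulate_4c_counts()] into reads: each read is the viewpoint
#' reading primer followed by the captured frag-end sequence — plus-strand
#' for left-side frag-ends and reverse-complement for right-side ones, as
#' the inward-reading primer would produce. Read order is shuffled.
#'
#' @inheritParams simulate_4c_counts
#' @return A named list, one character vector of reads per replicate.
#' @export
simulate_4c_reads <- function(library, config, genotype,
                              n_replicates = config$n_replicates,
                              seed = subseed(config$seed, "4c", genotype)) {
  counts <- simulate_4c_counts(library, config, genotype, n_replicates, seed)
  primer <- config$vp$reading_primer
  captured <- ifelse(library$side == "left_of_fragment",
                     library$sequence, revcomp(library$sequence))
  templates <- paste0(primer, captured)
  out <- lapply(seq_len(ncol(counts)), function(j) {
    reads <- rep.int(templates, counts[, j])
    sample(reads)
  })
  names(out) <- colnames(counts)
  out
}

#' Simulate an expression cohort
#'
#' Per sample, each gene's quantity is
#' `baseline x genotype multiplier x log-normal measurement noise (CV) x
#' per-sample loading scale`; reference genes always carry multiplier 1.
#' With `cv = 0` and `sample_scale_cv = 0` the quantities are exact.
#'
#' @param config A [sim_config()] (its `expression` block is used).
#' @param genotypes Genotypes to simulate (default `config$genotypes`).
#' @param n_per_genotype Samples per genotype (default from the block).
#' @param seed Seed (default derived from `config$seed`).
#' @return Long-format data.frame `gene`, `sample`, `genotype`, `tissue`,
#'   `quantity`, ready for [normalize_expression()].
#' @export
simulate_expression <- function(config, genotypes = config$genotypes,
                                n_per_genotype = config$expression$n_per_genotype,
                                seed = subseed(config$seed, "expr")) {
  ex <- config$expression
  set.seed(seed)
  lognoise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- list()
  for (g in genotypes) {
    eff <- ex$effects[[g]]
    for (r in seq_len(n_per_genotype)) {
      sample_id <- paste0(g, "_s", r)
      scale <- lognoise(1, ex$sample_scale_cv)
      mult <- rep(1, nrow(ex$genes))
      if (!is.null(eff)) {
        m <- match(ex$genes$gene, names(eff))
        mult[!is.na(m)] <- eff[m[!is.na(m)]]
      }
      mult[ex$genes$gene %in% ex$reference_genes] <- 1
      q <- ex$genes$baseline * mult * lognoise(nrow(ex$genes), ex$cv) * scale
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ex$genes$gene, sample = sample_id, genotype = g,
        tissue = "ventricle", quantity = q
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a full simulated scenario to disk
#'
#' Materializes the scenario as plain-text files: genome FASTA, frag-end
#' library BED, one FASTQ per genotype x replicate, the expression table
#' TSV, anchor centers TSV, and a JSON truth record (configuration and
#' effect regions) for parameter-recovery tests.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the genome, library and file paths.
#' @export
write_scenario <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  library <- build_fragend_library(genome, config$scheme)
  paths <- list(genome = file.path(outdir, "genome.fa"),
                fragends = file.path(outdir, "fragends.bed"),
                expression = file.path(outdir, "expression.tsv"),
                anchors = file.path(outdir, "anchor_centers.tsv"),
                truth = file.path(outdir, "truth.json"))
  write_genome_fasta(genome, paths$genome)
  write_fragends_bed(library, paths$fragends)
  reads <- list()
  for (g in config$genotypes) {
    rs <- simulate_4c_reads(library, config, g)
    for (nm in names(rs)) {
      fq <- file.path(outdir, paste0(nm, ".fq"))
      write_fastq(rs[[nm]], fq)
      reads[[nm]] <- fq
    }
  }
  paths$reads <- reads
  expr <- simulate_expression(config)
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(config$anchor_centers, paths$anchors, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    seed = config$seed,
    genotypes = config$genotypes,
    n_replicates = config$n_replicates,
    n_reads_cis = config$n_reads_cis,
    n_reads_trans = config$n_reads_trans,
    decay = list(scale = config$decay_scale,
                 exponent = config$decay_exponent,
                 background_floor = config$background_floor),
    effect_regions = config$effect_regions,
    viewpoint = list(name = config$vp$name, chrom = config$vp$chrom,
                     position = config$vp$position,
                     reading_primer = config$vp$reading_primer)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(genome = genome, library = library, paths = paths))
}
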