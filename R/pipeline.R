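# End-to-end orchestration: frag-end genome -> per-replicate profiles ->
# anchor tests, with a machine-readable manifest. Deterministic: rerunning
# with the same inputs reproduces byte-identical output tables.

#' Quantify one replicate: assign, filter, normalize
#'
#' Convenience chain [assign_reads()] -> [remove_top_fragend()] ->
#' [normalize_profile()], returning the normalized profile that anchor
#' analysis consumes.
#'
#' @param reads Reads (vector, DNAStringSet or FASTQ path).
#' @param vp A [viewpoint()].
#' @param library A `fragend_library`.
#' @param target Normalization target (default 1e6 intrachromosomal reads).
#' @return A normalized `coverage_profile`.
#' @export
quantify_replicate <- function(reads, vp, library, target = 1e6) {
  profile <- assign_reads(reads, vp, library)
  profile <- remove_top_fragend(profile)
  normalize_profile(profile, target = target)
}

#' Run the full contact-profile analysis
#'
#' Executes the pipeline over two replicate groups: build the frag-end
#' library from the genome, quantify and normalize each replicate, smooth
#' profiles for display, build anchors and test each for a group difference
#' in summed normalized coverage. When `outdir` is given, writes the
#' frag-end BED, per-replicate profile TSVs (normalized + smoothed values),
#' the anchor results TSV and a JSON manifest recording every parameter,
#' input checksums, read fates and scale factors; reruns are byte-identical.
#'
#' @param genome Named character vector / DNAStringSet, or a FASTA path.
#' @param reads_a,reads_b Lists (one element per replicate) of read vectors
#'   or FASTQ paths for groups A and B.
#' @param vp A [viewpoint()].
#' @param anchor_centers Data.frame `chrom`, `center` (+ optional `name`).
#' @param scheme A [restriction_scheme()].
#' @param halfwidth Anchor half-width (bp), default 5,000 (10 Kb anchors).
#' @param window Running-mean window, default 21 frag-ends.
#' @param target Intrachromosomal normalization target, default 1e6.
#' @param outdir Optional output directory.
#' @param group_names Labels for the two groups.
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed documents how inputs were generated).
#' @return A list of class `pipeline_result`: `library`, `profiles_a`,
#'   `profiles_b` (smoothed), `anchors`, `results`, `manifest`.
#' @export
run_pipeline <- function(genome, reads_a, reads_b, vp, anchor_centers,
                         scheme = restriction_scheme(), halfwidth = 5000L,
                         window = 21L, target = 1e6, outdir = NULL,
                         group_names = c("A", "B"), seed = NA_integer_) {
  input_paths <- character(0)
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    input_paths <- c(input_paths, genome = genome)
    genome <- read_genome_fasta(genome)
  }
  grab_paths <- function(reads, grp) {
    p <- unlist(Filter(function(r) is.character(r) && length(r) == 1L &&
                         file.exists(r), reads))
    if (length(p)) names(p) <- paste0(grp, "_", seq_along(p))
    p
  }
  input_paths <- c(input_paths, grab_paths(reads_a, group_names[1]),
                   grab_paths(reads_b, group_names[2]))

  library <- build_fragend_library(genome, scheme)
  quantify_group <- function(reads, grp) {
    for (r in reads) {
      # a length-1 string with non-nucleotide characters can only be a path
      if (is.character(r) && length(r) == 1L && !file.exists(r) &&
          grepl("[^ACGTNacgtn]", r)) {
        stop("quantify: reads file not found: ", r)
      }
    }
    profs <- lapply(reads, quantify_replicate, vp = vp, library = library,
                    target = target)
    names(profs) <- paste0(grp, "_rep", seq_along(profs))
    profs
  }
  profiles_a <- quantify_group(reads_a, group_names[1])
  profiles_b <- quantify_group(reads_b, group_names[2])
  anchors <- build_anchors(anchor_centers, library, halfwidth = halfwidth)
  results <- differential_contacts(profiles_a, profiles_b, anchors)
  smoothed_a <- lapply(profiles_a, running_mean, window = window)
  smoothed_b <- lapply(profiles_b, running_mean, window = window)

  manifest <- list(
    package = "fourc",
    version = as.character(utils::packageVersion("fourc")),
    seed = seed,
    parameters = list(
      primary_motif = scheme$primary, secondary_motif = scheme$secondary,
      extract_len = scheme$extract_len, window = window,
      halfwidth = halfwidth, anchor_width = 2L * halfwidth,
      normalization_target = target,
      viewpoint = list(name = vp$name, chrom = vp$chrom,
                       position = vp$position,
                       reading_primer = vp$reading_primer)
    ),
    inputs = if (length(input_paths)) {
      lapply(input_paths, function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
    } else list(),
    n_fragends = nrow(library),
    n_unique_fragends = sum(library$is_unique),
    read_fates = lapply(c(profiles_a, profiles_b), function(p)
      c(as.list(p$discarded), assigned = p$total_reads)),
    scale_factors = lapply(c(profiles_a, profiles_b), `[[`, "scale_factor"),
    removed_fragends = lapply(c(profiles_a, profiles_b),
                              function(p) p$removed_fragend$id)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fragends_bed(library, file.path(outdir, "fragends.bed"))
    prof_dir <- file.path(outdir, "profiles")
    dir.create(prof_dir, showWarnings = FALSE)
    for (nm in names(smoothed_a)) {
      write_profile_tsv(smoothed_a[[nm]], file.path(prof_dir, paste0(nm, ".tsv")))
    }
    for (nm in names(smoothed_b)) {
      write_profile_tsv(smoothed_b[[nm]], file.path(prof_dir, paste0(nm, ".tsv")))
    }
    write_anchor_results(results, file.path(outdir, "anchor_results.tsv"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(
    list(library = library, profiles_a = smoothed_a, profiles_b = smoothed_b,
         anchors = anchors, results = results, manifest = manifest),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: ", nrow(x$library), " frag-ends, ",
      length(x$profiles_a), " + ", length(x$profiles_b), " replicates, ",
      nrow(x$results), " anchors tested\n", sep = "")
  sig <- sum(x$results$p_value < 0.05)
  cat("  anchors with raw p < 0.05: ", sig, "\n", sep = "")
  invisible(x)
}

#' Simulate the default scenario and run the full pipeline on it
#'
#' The end-to-end driver: generates the genome and per-replicate read sets
#' for both genotypes from `config`, then runs [run_pipeline()] with the
#' configuration's anchors and constants. With the default [sim_config()]
#' this reproduces, on synthetic data, the design of a
#' wildtype-versus-heterozygous-enhancer-deletion 4C comparison: a
#' contact-profile pair with one region at half weight in the mutant, and
#' anchor t tests that should flag exactly that region.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory (passed to [run_pipeline()]).
#' @param read_level Simulate FASTQ-style reads and run the full
#'   primer-matching assignment (TRUE, default); FALSE short-circuits to
#'   count-level profiles (identical result for error-free reads, much
#'   faster for Monte-Carlo studies).
#' @return A `pipeline_result` (plus `$config`).
#' @export
run_scenario <- function(config = sim_config(), outdir = NULL,
                         read_level = TRUE) {
  genome <- simulate_genome(config)
  if (read_level) {
    library <- build_fragend_library(genome, config$scheme)
    reads_a <- simulate_4c_reads(library, config, config$genotypes[1])
    reads_b <- simulate_4c_reads(library, config, config$genotypes[2])
    res <- run_pipeline(genome, reads_a, reads_b, config$vp,
                        config$anchor_centers, scheme = config$scheme,
                        halfwidth = config$halfwidth, window = config$window,
                        target = config$norm_target, outdir = outdir,
                        group_names = config$genotypes, seed = config$seed)
  } else {
    library <- build_fragend_library(genome, config$scheme)
    uniq <- library$is_unique
    prof_group <- function(genotype) {
      counts <- simulate_4c_counts(library, config, genotype)
      profs <- lapply(seq_len(ncol(counts)), function(j) {
        p <- profile_from_counts(counts[uniq, j], config$vp, library)
        normalize_profile(remove_top_fragend(p), target = config$norm_target)
      })
      names(profs) <- colnames(counts)
      profs
    }
    profiles_a <- prof_group(config$genotypes[1])
    profiles_b <- prof_group(config$genotypes[2])
    anchors <- build_anchors(config$anchor_centers, library,
                             halfwidth = config$halfwidth)
    results <- differential_contacts(profiles_a, profiles_b, anchors)
    res <- structure(
      list(library = library, profiles_a = profiles_a,
           profiles_b = profiles_b, anchors = anchors, results = results,
           manifest = list(seed = config$seed, count_level = TRUE)),
      class = "pipeline_result"
    )
  }
  res$config <- config
  res
}
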