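# Read assignment, filtering, normalization and running-mean smoothing of
# one-viewpoint 4C coverage profiles.

#' Define a 4C viewpoint
#'
#' A viewpoint is the fixed genomic position whose contacts the 4C library
#' measures, identified operationally by its inverse-PCR reading primer: a
#' read belongs to this viewpoint iff it starts with the reading primer, and
#' the sequence that follows is the captured frag-end.
#'
#' @param name Viewpoint label.
#' @param chrom Chromosome of the viewpoint (its chromosome defines
#'   cis/intrachromosomal for normalization).
#' @param position 0-based bp position of the viewpoint.
#' @param reading_primer Reading-primer sequence (non-empty, uppercase ACGT).
#' @param nonreading_primer Optional non-reading primer, kept as metadata.
#' @return An object of class `viewpoint`.
#' @export
viewpoint <- function(name, chrom, position, reading_primer,
                      nonreading_primer = NA_character_) {
  if (!is.character(reading_primer) || length(reading_primer) != 1L ||
      nchar(reading_primer) == 0L) {
    stop("'reading_primer' must be a non-empty string")
  }
  structure(
    list(name = name, chrom = chrom, position = as.integer(position),
         reading_primer = toupper(reading_primer),
         nonreading_primer = nonreading_primer),
    class = "viewpoint"
  )
}

#' @export
print.viewpoint <- function(x, ...) {
  cat("viewpoint '", x$name, "' at ", x$chrom, ":", x$position,
      " (reading primer ", x$reading_primer, ")\n", sep = "")
  invisible(x)
}

#' Assign primer-tagged reads to frag-ends
#'
#' A read is assigned to frag-end `f` iff it begins with the viewpoint's
#' reading primer (exact match) and, after removing the primer, its next
#' `k` bases (`k = min(remaining length, extract_len)`) exactly equal `f`'s
#' sequence or its reverse complement. Reads failing the primer match are
#' tallied as `no_primer`; reads whose captured sequence belongs to a
#' non-unique frag-end are discarded as `non_unique` (non-unique frag-ends
#' are excluded from all downstream analysis); reads matching nothing are
#' `no_match`. Exact matching (no mismatch tolerance) stands in for
#' alignment: the synthetic reads this pipeline quantifies are error-free,
#' so the frag-end assignment semantics are preserved without an aligner.
#'
#' @param reads Character vector of read sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTQ file.
#' @param vp A [viewpoint()].
#' @param library A `fragend_library` with uniqueness flags (see
#'   [mark_unique()]).
#' @return A `coverage_profile` in state `"raw"`: counts over the unique
#'   frag-ends of the library, read-fate tallies in `$discarded`, and
#'   `total_reads` = number of assigned reads.
#' @export
assign_reads <- function(reads, vp, library) {
  stopifnot(inherits(vp, "viewpoint"))
  if (is.null(library) || nrow(library) == 0L) stop("empty frag-end library")
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  reads <- toupper(reads)
  scheme <- attr(library, "scheme")
  extract_len <- if (is.null(scheme)) max(nchar(library$sequence)) else scheme$extract_len

  primer <- vp$reading_primer
  np <- nchar(primer)
  has_primer <- startsWith(reads, primer)
  captured <- substr(reads[has_primer], np + 1L, np + extract_len)

  uniq <- library[library$is_unique, , drop = FALSE]
  # lookup: forward and reverse-complement sequence -> row in `uniq`;
  # sequences of non-unique frag-ends -> 0 so their reads are discarded as
  # such; keys claimed by both a unique and a non-unique frag-end (or by two
  # unique frag-ends via reverse-complement coincidence) are ambiguous -> 0
  fwd <- toupper(uniq$sequence)
  keys <- c(fwd, revcomp(fwd))
  vals <- rep.int(seq_len(nrow(uniq)), 2L)
  # palindromic frag-ends contribute the same (key, row) pair twice
  pair_dup <- duplicated(paste0(keys, "\r", vals))
  keys <- keys[!pair_dup]
  vals <- vals[!pair_dup]
  # a key claimed by two different frag-ends (reverse-complement coincidence)
  # is ambiguous and cannot be assigned
  vals[keys %in% unique(keys[duplicated(keys)])] <- 0L
  bad <- unique(toupper(library$sequence[!library$is_unique]))
  bad <- unique(c(bad, revcomp(bad)))
  keys <- c(bad, keys)            # non-unique sequences take precedence
  vals <- c(rep(0L, length(bad)), vals)
  keep <- !duplicated(keys)
  keys <- keys[keep]
  vals <- vals[keep]

  hit <- vals[match(captured, keys)]
  assigned <- hit[!is.na(hit) & hit > 0L]
  counts <- tabulate(assigned, nbins = nrow(uniq))
  discarded <- c(
    no_primer = sum(!has_primer),
    no_match = sum(is.na(hit)),
    non_unique = sum(!is.na(hit) & hit == 0L)
  )
  new_coverage_profile(
    viewpoint = vp,
    fragends = uniq[, c("id", "chrom", "pos", "side")],
    counts = as.numeric(counts),
    state = "raw",
    total_reads = length(assigned),
    discarded = discarded
  )
}

revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

new_coverage_profile <- function(viewpoint, fragends, counts, state,
                                 total_reads = NA_integer_,
                                 discarded = NULL, scale_factor = NA_real_,
                                 removed_fragend = NULL, smoothed = NULL,
                                 window = NA_integer_) {
  stopifnot(nrow(fragends) == length(counts))
  structure(
    list(viewpoint = viewpoint, fragends = fragends, counts = counts,
         state = state, total_reads = total_reads, discarded = discarded,
         scale_factor = scale_factor, removed_fragend = removed_fragend,
         smoothed = smoothed, window = window),
    class = "coverage_profile"
  )
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("coverage_profile [", x$state, "] for viewpoint '", x$viewpoint$name,
      "': ", nrow(x$fragends), " frag-ends, ",
      format(sum(x$counts), big.mark = ","), " total coverage\n", sep = "")
  invisible(x)
}

#' Coverage profile from precomputed frag-end counts
#'
#' Entry point for count-level simulation and testing: wraps a vector of
#' per-frag-end read counts (aligned with the unique frag-ends of `library`)
#' as a raw `coverage_profile`, exactly as [assign_reads()] would produce
#' from error-free reads.
#'
#' @param counts Non-negative numeric vector, one value per unique frag-end
#'   of `library` (library order).
#' @param vp A [viewpoint()].
#' @param library A `fragend_library`.
#' @return A `coverage_profile` in state `"raw"`.
#' @export
profile_from_counts <- function(counts, vp, library) {
  uniq <- library[library$is_unique, , drop = FALSE]
  if (length(counts) != nrow(uniq)) {
    stop("'counts' must have one value per unique frag-end (",
         nrow(uniq), "), got ", length(counts))
  }
  if (any(counts < 0)) stop("negative counts")
  new_coverage_profile(
    viewpoint = vp,
    fragends = uniq[, c("id", "chrom", "pos", "side")],
    counts = as.numeric(counts),
    state = "raw",
    total_reads = sum(counts),
    discarded = c(no_primer = 0L, no_match = 0L, non_unique = 0L)
  )
}

#' Remove the highest-coverage frag-end
#'
#' Removes exactly one frag-end — the genome-wide maximum count (in practice
#' the viewpoint's own frag-end) — before normalization. Ties are broken by
#' lowest genomic coordinate, then chromosome name order, so the operation
#' is deterministic. The removed frag-end is recorded in
#' `$removed_fragend`.
#'
#' @param profile A raw `coverage_profile`.
#' @return The profile in state `"filtered"`, one frag-end shorter.
#' @export
remove_top_fragend <- function(profile) {
  check_state(profile, "raw")
  if (all(profile$counts == 0)) stop("empty profile: all frag-end counts are zero")
  ord <- order(-profile$counts, profile$fragends$pos, profile$fragends$chrom)
  top <- ord[1L]
  removed <- c(as.list(profile$fragends[top, ]), count = profile$counts[top])
  profile$fragends <- profile$fragends[-top, , drop = FALSE]
  profile$counts <- profile$counts[-top]
  profile$removed_fragend <- removed
  profile$state <- "filtered"
  profile
}

#' Read-depth normalize to a fixed intrachromosomal total
#'
#' Scales every frag-end count (cis and trans) by
#' `s = target / sum(cis counts)`, where cis means the viewpoint's
#' chromosome, so that the post-normalization intrachromosomal coverage sums
#' to `target` (1 million by default). The highest-coverage frag-end must
#' already have been removed ([remove_top_fragend()]); its count is thereby
#' excluded from the cis sum.
#'
#' @param profile A filtered `coverage_profile`.
#' @param target Normalization target for the intrachromosomal sum
#'   (default 1e6).
#' @return The profile in state `"normalized"`, with `$scale_factor = s`.
#' @export
normalize_profile <- function(profile, target = 1e6) {
  check_state(profile, "filtered")
  cis <- profile$fragends$chrom == profile$viewpoint$chrom
  cis_sum <- sum(profile$counts[cis])
  if (cis_sum <= 0) stop("no intrachromosomal signal: cis coverage sum is zero")
  s <- target / cis_sum
  profile$counts <- profile$counts * s
  profile$scale_factor <- s
  profile$state <- "normalized"
  profile
}

#' Running-mean smoothing of a normalized profile
#'
#' Replaces the value at each frag-end by the mean of the `window`
#' (default 21) consecutive frag-ends centred on it, per chromosome
#' independently (frag-ends ordered by genomic coordinate). Within
#' `(window - 1) / 2` positions of a chromosome edge the window shrinks
#' symmetrically to the largest centred window that fits (minimum 1);
#' mirrored or zero-padded edges would fabricate signal.
#'
#' @param profile A normalized `coverage_profile`.
#' @param window Odd positive integer window width, default 21.
#' @return The profile in state `"smoothed"`; smoothed values in
#'   `$smoothed`, normalized values retained in `$counts`.
#' @export
running_mean <- function(profile, window = 21L) {
  check_state(profile, "normalized")
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L ||
      window %% 2L == 0L) {
    stop("'window' must be a single odd positive integer")
  }
  ord <- order(profile$fragends$chrom, profile$fragends$pos)
  if (is.unsorted(ord)) {
    profile$fragends <- profile$fragends[ord, , drop = FALSE]
    profile$counts <- profile$counts[ord]
  }
  sm <- numeric(length(profile$counts))
  for (chrom in unique(profile$fragends$chrom)) {
    i <- which(profile$fragends$chrom == chrom)
    sm[i] <- running_mean_vec(profile$counts[i], window)
  }
  profile$smoothed <- sm
  profile$window <- window
  profile$state <- "smoothed"
  profile
}

# shrinking centred running mean of a plain vector (exported for testing
# against a naive sliding-window oracle)
#' Shrinking centred running mean of a numeric vector
#'
#' At interior positions this is the ordinary mean over the `window` values
#' centred at each position; within `(window - 1) / 2` positions of either
#' end the window shrinks symmetrically to the largest centred window that
#' fits.
#'
#' @param x Numeric vector.
#' @param window Odd positive integer.
#' @return Numeric vector of the same length.
#' @export
running_mean_vec <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  h <- (window - 1L) %/% 2L
  i <- seq_len(n)
  hi <- pmin(h, i - 1L, n - i)
  cs <- cumsum(c(0, x))
  (cs[i + hi + 1L] - cs[i - hi]) / (2 * hi + 1)
}

check_state <- function(profile, expected) {
  if (!inherits(profile, "coverage_profile")) {
    stop("expected a coverage_profile")
  }
  if (profile$state != expected) {
    stop("profile state must be '", expected, "', got '", profile$state, "'")
  }
  invisible(profile)
}

#' Read a FASTQ file as a character vector of sequences
#'
#' Four-line records; quality lines are ignored.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as.character(unname(x))
}

#' Write reads as a FASTQ file with constant quality
#'
#' @param reads Character vector of read sequences.
#' @param path Output path.
#' @param quality Single quality character replicated per base (default
#'   "I", Phred 40).
#' @export
write_fastq <- function(reads, path, quality = "I") {
  n <- length(reads)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (n > 0L) {
    lines <- character(4L * n)
    lines[seq(1L, 4L * n, by = 4L)] <- paste0("@read", seq_len(n))
    lines[seq(2L, 4L * n, by = 4L)] <- reads
    lines[seq(3L, 4L * n, by = 4L)] <- "+"
    lines[seq(4L, 4L * n, by = 4L)] <- strrep(quality, nchar(reads))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Write a coverage profile as TSV
#'
#' One row per frag-end with raw-state-dependent columns: `chrom`, `pos`,
#' `fragend_id`, `count` and, when present, `smoothed`.
#'
#' @param profile A `coverage_profile` in any state.
#' @param path Output path.
#' @export
write_profile_tsv <- function(profile, path) {
  tab <- data.frame(
    chrom = profile$fragends$chrom,
    pos = profile$fragends$pos,
    fragend_id = profile$fragends$id,
    count = profile$counts
  )
  if (!is.null(profile$smoothed)) tab$smoothed <- profile$smoothed
  utils::write.table(format(tab, digits = 15, scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a coverage profile track as bedGraph
#'
#' Each frag-end is represented as a 1-bp interval at its boundary position
#' carrying the profile value for the requested state.
#'
#' @param profile A `coverage_profile`.
#' @param path Output path.
#' @param value `"count"` (raw/filtered/normalized values) or `"smoothed"`.
#' @export
write_profile_bedgraph <- function(profile, path, value = c("count", "smoothed")) {
  value <- match.arg(value)
  v <- if (value == "smoothed") {
    if (is.null(profile$smoothed)) stop("profile has no smoothed values")
    profile$smoothed
  } else {
    profile$counts
  }
  bg <- data.frame(
    chrom = profile$fragends$chrom,
    start = profile$fragends$pos,
    end = profile$fragends$pos + 1L,
    value = v
  )
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s_%s\"",
                     profile$viewpoint$name, value), con)
  utils::write.table(bg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
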