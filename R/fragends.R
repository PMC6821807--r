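# In-silico restriction digestion and the frag-end reduced genome.
#
# All genomic coordinates in this package are 0-based, half-open ([start, end)),
# matching BED. A "frag-end" is the stretch of sequence directly flanking a
# primary restriction site, read inward into the fragment; frag-ends are the
# mapping units of the reduced genome used for 4C-seq quantification.

#' Restriction scheme for the double digestion
#'
#' Bundles the primary and secondary restriction motifs and the length of
#' sequence extracted at each primary cut site. Defaults correspond to a
#' DpnII (GATC) primary and Csp6I (GTAC) secondary digestion with 36 bp
#' frag-ends (a typical trimmed-read length).
#'
#' Cuts are placed at the motif start for both enzymes. For the primary
#' enzyme this matches DpnII's blunt `^GATC` cut; for the secondary enzyme
#' only the presence of a site within a fragment matters (the blind-fragment
#' flag), so the true cut offset is irrelevant downstream.
#'
#' @param primary Primary restriction motif (uppercase ACGT), default "GATC".
#' @param secondary Secondary restriction motif, default "GTAC".
#' @param extract_len Length in bp of the frag-end sequence extracted at each
#'   primary cut site; must be at least `nchar(primary)`.
#' @return An object of class `restriction_scheme`.
#' @export
restriction_scheme <- function(primary = "GATC", secondary = "GTAC",
                               extract_len = 36L) {
  check_motif(primary, "primary")
  check_motif(secondary, "secondary")
  extract_len <- as.integer(extract_len)
  if (length(extract_len) != 1L || is.na(extract_len) ||
      extract_len < nchar(primary)) {
    stop("'extract_len' must be a single integer >= nchar(primary)")
  }
  structure(
    list(primary = primary, secondary = secondary, extract_len = extract_len),
    class = "restriction_scheme"
  )
}

check_motif <- function(motif, what) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    stop("invalid restriction scheme: ", what, " motif must be a non-empty string")
  }
  if (grepl("[^ACGT]", motif)) {
    stop("invalid restriction scheme: ", what,
         " motif contains characters outside ACGT: ", motif)
  }
  invisible(motif)
}

#' @export
print.restriction_scheme <- function(x, ...) {
  cat("restriction scheme: primary ", x$primary, ", secondary ", x$secondary,
      ", extract_len ", x$extract_len, " bp\n", sep = "")
  invisible(x)
}

#' Digest a sequence at every occurrence of a restriction motif
#'
#' Scans the sequence left to right for all (possibly overlapping) motif
#' occurrences and cuts at each occurrence start. Motifs never match across
#' an `N` base.
#'
#' @param genome_seq A single nucleotide sequence (character or
#'   [Biostrings::DNAString]).
#' @param motif Restriction motif, uppercase ACGT.
#' @return A data.frame with columns `start`, `end` (0-based, half-open) and
#'   `index` (ordinal along the sequence). Fragments tile `[0, nchar)` exactly;
#'   a cut at position 0 does not produce an empty leading fragment.
#' @export
digest <- function(genome_seq, motif) {
  check_motif(motif, "digestion")
  seq_str <- as.character(genome_seq)
  if (length(seq_str) != 1L || nchar(seq_str) == 0L) {
    stop("'genome_seq' must be a single non-empty sequence")
  }
  cuts <- motif_starts(seq_str, motif)
  len <- nchar(seq_str)
  bounds <- sort(unique(c(0L, cuts, len)))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  keep <- starts < ends
  data.frame(
    start = starts[keep],
    end = ends[keep],
    index = seq_len(sum(keep))
  )
}

# 0-based start coordinates of all (overlapping) occurrences of `motif`.
# Biostrings::matchPattern with fixed = TRUE treats N in the subject as
# matching nothing, which is the behaviour we want.
motif_starts <- function(seq_str, motif) {
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(seq_str),
                                fixed = TRUE)
  as.integer(Biostrings::start(m)) - 1L
}

#' Build the frag-end library from a genome
#'
#' Digests every chromosome with the primary motif and emits, for each
#' fragment boundary that abuts a primary cut site, the frag-end sequence:
#' the first `extract_len` bases of the fragment read inward from that
#' boundary, truncated at the opposite fragment boundary. Chromosome termini
#' that are not cut sites yield no frag-end. Fragments containing no
#' secondary-motif occurrence are flagged blind (`is_blind`); blind
#' frag-ends are retained by default throughout the pipeline.
#'
#' Frag-end sequences are stored as plus-strand genome text read inward
#' (left-side frag-ends read rightward; right-side frag-ends keep the
#' plus-strand text of the fragment's last bases). Reverse-complement
#' matching is handled at read assignment.
#'
#' Uniqueness flags are populated by [mark_unique()], which this function
#' calls; non-unique frag-ends stay in the library but are discarded at
#' read assignment.
#'
#' @param genome A named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences; names must be unique.
#' @param scheme A [restriction_scheme()].
#' @return A data.frame of class `fragend_library` with one row per frag-end:
#'   `id`, `chrom`, `pos` (the primary-site boundary the frag-end flanks),
#'   `side` (`"left_of_fragment"`/`"right_of_fragment"`), `start`, `end`
#'   (interval covered by the extracted sequence), `fragment_index`,
#'   `fragment_start`, `fragment_end`, `sequence`, `is_blind`, `is_unique`.
#'   Rows are ordered by chromosome (input order) then position. Chromosome
#'   lengths are kept in attribute `chrom_lengths`.
#' @export
build_fragend_library <- function(genome, scheme = restriction_scheme()) {
  stopifnot(inherits(scheme, "restriction_scheme"))
  if (length(genome) == 0L) stop("empty genome")
  genome <- as_genome(genome)
  per_chrom <- lapply(names(genome), function(chrom) {
    fragends_one_chrom(chrom, genome[[chrom]], scheme)
  })
  lib <- do.call(rbind, per_chrom)
  rownames(lib) <- NULL
  if (nrow(lib) > 0L) {
    lib$id <- paste0(lib$chrom, ":", lib$pos, ":",
                     ifelse(lib$side == "left_of_fragment", "L", "R"))
  } else {
    lib$id <- character(0)
  }
  lib <- lib[, c("id", "chrom", "pos", "side", "start", "end",
                 "fragment_index", "fragment_start", "fragment_end",
                 "sequence", "is_blind", "is_unique")]
  attr(lib, "chrom_lengths") <- vapply(genome, nchar, integer(1))
  attr(lib, "scheme") <- scheme
  class(lib) <- c("fragend_library", "data.frame")
  mark_unique(lib)
}

as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- as.character(genome)
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome)) || any(names(genome) == "")) {
    stop("'genome' must be a named character vector or DNAStringSet with unique names")
  }
  if (any(nchar(genome) == 0L)) stop("empty chromosome sequence in genome")
  toupper(genome)
}

fragends_one_chrom <- function(chrom, seq_str, scheme) {
  frags <- digest(seq_str, scheme$primary)
  cuts <- motif_starts(seq_str, scheme$primary)
  len <- nchar(seq_str)
  sec <- motif_starts(seq_str, scheme$secondary)
  sec_len <- nchar(scheme$secondary)
  # a fragment is blind iff no secondary occurrence lies fully inside it;
  # fragments tile the chromosome, so each occurrence start falls in exactly one
  blind <- rep(TRUE, nrow(frags))
  if (length(sec) > 0L) {
    idx <- findInterval(sec, frags$start)
    inside <- sec + sec_len <= frags$end[idx]
    blind[unique(idx[inside])] <- FALSE
  }
  el <- scheme$extract_len
  # every internal fragment boundary is a primary cut; the chromosome start is
  # one only if a motif sits at position 0, and the chromosome end never is
  # (cut positions are motif starts, strictly < len)
  li <- which(frags$start != 0L | 0L %in% cuts)
  ri <- which(frags$end != len)
  mk <- function(i, side) {
    if (length(i) == 0L) return(NULL)
    s <- frags$start[i]; e <- frags$end[i]
    if (side == "left_of_fragment") {
      fs <- s; fe <- pmin(s + el, e); pos <- s
    } else {
      fs <- pmax(e - el, s); fe <- e; pos <- e
    }
    data.frame(
      chrom = chrom, pos = pos, side = side, start = fs, end = fe,
      fragment_index = frags$index[i], fragment_start = s, fragment_end = e,
      sequence = substring(seq_str, fs + 1L, fe),
      is_blind = blind[i], is_unique = NA
    )
  }
  res <- rbind(mk(li, "left_of_fragment"), mk(ri, "right_of_fragment"))
  if (is.null(res)) {
    return(data.frame(
      chrom = character(0), pos = integer(0), side = character(0),
      start = integer(0), end = integer(0), fragment_index = integer(0),
      fragment_start = integer(0), fragment_end = integer(0),
      sequence = character(0), is_blind = logical(0), is_unique = logical(0)
    ))
  }
  res[order(res$pos, res$side), , drop = FALSE]
}

#' Flag non-unique frag-ends
#'
#' A frag-end is unique iff its sequence occurs exactly once among all
#' frag-end sequences in the library (case-insensitive exact comparison).
#' Frag-end sequences containing `N` are conservatively marked non-unique,
#' mirroring unmappable genomic regions. Library order is preserved and the
#' operation is idempotent.
#'
#' @param library A `fragend_library` (or any data.frame with a `sequence`
#'   column).
#' @return The library with `is_unique` filled in.
#' @export
mark_unique <- function(library) {
  seqs <- tolower(library$sequence)
  dup <- duplicated(seqs) | duplicated(seqs, fromLast = TRUE)
  has_n <- grepl("n", seqs, fixed = TRUE)
  library$is_unique <- !dup & !has_n
  library
}

#' @export
print.fragend_library <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat("fragend_library: ", nrow(x), " frag-ends on ", length(cl),
      " chromosome(s); ", sum(x$is_unique), " unique, ",
      sum(x$is_blind), " blind\n", sep = "")
  invisible(x)
}

#' Read a multi-record FASTA file as a genome
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' uppercase character vector, the representation the digestion functions
#' accept directly. Record names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file (wrapped lines allowed).
#' @return Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as_genome(x)
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector or DNAStringSet.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- as_genome(genome)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Write a frag-end library as BED6 plus annotation columns
#'
#' Emits one BED line per frag-end covering the extracted-sequence interval,
#' strand `+` for left-side (rightward-reading) and `-` for right-side
#' frag-ends, followed by `sequence`, `unique` and `blind` columns.
#'
#' @param library A `fragend_library`.
#' @param path Output path.
#' @export
write_fragends_bed <- function(library, path) {
  bed <- data.frame(
    chrom = library$chrom,
    start = library$start,
    end = library$end,
    name = library$id,
    score = 0L,
    strand = ifelse(library$side == "left_of_fragment", "+", "-"),
    sequence = library$sequence,
    unique = as.integer(library$is_unique),
    blind = as.integer(library$is_blind)
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write frag-end sequences as FASTA
#'
#' @param library A `fragend_library`.
#' @param path Output path.
#' @export
write_fragends_fasta <- function(library, path) {
  seqs <- Biostrings::DNAStringSet(library$sequence)
  names(seqs) <- library$id
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
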