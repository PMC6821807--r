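# Independent oracles and tiny fixture builders shared across the suite.
# Oracles are deliberately naive (O(n*m) scans, explicit loops, closed
# forms) and never call the pipeline code they check.

# all 0-based start positions of `motif` in `s` by exhaustive scan
oracle_motif_scan <- function(s, motif) {
  n <- nchar(s); m <- nchar(motif)
  hits <- integer(0)
  if (m > n) return(hits)
  for (i in seq_len(n - m + 1L)) {
    if (substr(s, i, i + m - 1L) == motif) hits <- c(hits, i - 1L)
  }
  hits
}

# fragments implied by a cut-position set, as (start, end) rows
oracle_fragments <- function(s, motif) {
  cuts <- oracle_motif_scan(s, motif)
  bounds <- sort(unique(c(0L, cuts, nchar(s))))
  out <- NULL
  for (i in seq_len(length(bounds) - 1L)) {
    if (bounds[i] < bounds[i + 1L]) {
      out <- rbind(out, c(bounds[i], bounds[i + 1L]))
    }
  }
  out
}

# shrinking centred sliding mean by explicit loop
oracle_running_mean <- function(x, window) {
  n <- length(x)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    hi <- min(h, i - 1L, n - i)
    out[i] <- mean(x[(i - hi):(i + hi)])
  }
  out
}

# textbook pooled-variance two-sample t, coded directly from the formula
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, dof = na + nb - 2, p = 2 * pt(-abs(t), na + nb - 2))
}

# brute-force anchor sum: filter every frag-end, then add
oracle_anchor_sum <- function(values, chroms, positions, anchor_chrom,
                              start, end) {
  total <- 0
  for (i in seq_along(values)) {
    if (chroms[i] == anchor_chrom && positions[i] >= start &&
        positions[i] < end) {
      total <- total + values[i]
    }
  }
  total
}

# random A/C/G/T sequence for oracle comparisons
random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# hand-built two-chromosome toy genome with known GATC/GTAC placement:
# chr1: 20 A's | GATC | 12 A's | GTAC | 14 A's | GATC | 30 C's  (len 88)
# chr2: 10 T's | GATC | 40 G's                                  (len 54)
toy_genome <- function() {
  c(chr1 = paste0(strrep("A", 20), "GATC", strrep("A", 12), "GTAC",
                  strrep("A", 14), "GATC", strrep("C", 30)),
    chr2 = paste0(strrep("T", 10), "GATC", strrep("G", 40)))
}

# small scrambled-sequence genome giving many distinct frag-ends
random_genome <- function(n_chrom = 2, len = 6000, seed = 42) {
  set.seed(seed)
  g <- vapply(seq_len(n_chrom), function(i) random_seq(len), character(1))
  names(g) <- paste0("chr", seq_len(n_chrom))
  g
}

# normalized coverage profile with prescribed values, for smoothing and
# anchor tests that need a profile in a given state
make_normalized_profile <- function(values, chroms, positions,
                                    vp_chrom = chroms[1]) {
  vp <- fourc::viewpoint("test_vp", vp_chrom, 0L, "GATC")
  fragends <- data.frame(
    id = paste0("fe", seq_along(values)),
    chrom = chroms, pos = positions, side = "left_of_fragment"
  )
  fourc:::new_coverage_profile(
    viewpoint = vp, fragends = fragends, counts = as.numeric(values),
    state = "normalized", scale_factor = 1
  )
}
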