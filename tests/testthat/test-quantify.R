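# Read assignment, top-frag-end removal, normalization and smoothing.

quant_fixture <- function() {
  g <- random_genome(n_chrom = 2, len = 5000, seed = 7)
  scheme <- restriction_scheme(extract_len = 20L)
  lib <- build_fragend_library(g, scheme)
  vp <- viewpoint("vp", "chr1", 2500L, reading_primer = "GTCCCAAGGGCACACTGATC")
  list(genome = g, scheme = scheme, lib = lib, vp = vp)
}

test_that("reads are assigned by primer plus exact frag-end match", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  target <- uniq[10, ]
  reads <- c(
    paste0(fx$vp$reading_primer, target$sequence),          # assigned
    paste0("TTTTTTTTTT", target$sequence),                  # no primer
    paste0(fx$vp$reading_primer, strrep("A", 20))           # matches nothing
  )
  prof <- assign_reads(reads, fx$vp, fx$lib)
  expect_s3_class(prof, "coverage_profile")
  expect_equal(prof$state, "raw")
  expect_equal(prof$total_reads, 1)
  expect_equal(sum(prof$counts), 1)
  expect_equal(prof$counts[prof$fragends$id == target$id], 1)
  expect_equal(unname(prof$discarded["no_primer"]), 1L)
  expect_equal(unname(prof$discarded["no_match"]), 1L)
  # conservation: assigned + discarded = input reads
  expect_equal(prof$total_reads + sum(prof$discarded), length(reads))
})

test_that("reverse-complement captured sequences are assigned too", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  target <- uniq[5, ]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(target$sequence)))
  prof <- assign_reads(paste0(fx$vp$reading_primer, rc), fx$vp, fx$lib)
  expect_equal(prof$counts[prof$fragends$id == target$id], 1)
})

test_that("reads matching a non-unique frag-end are discarded", {
  scheme <- restriction_scheme(extract_len = 8L)
  # two identical fragments -> identical frag-end sequences -> non-unique
  g <- c(chrA = paste0(strrep("T", 12), "GATCAAAAAAAA",
                       "GATCAAAAAAAA", "GATCCCTTTTTT", strrep("T", 12)))
  lib <- build_fragend_library(g, scheme)
  expect_true(any(!lib$is_unique))
  vp <- viewpoint("vp", "chrA", 0L, "GGGG")
  prof <- assign_reads("GGGGGATCAAAA", vp, lib)
  expect_equal(prof$total_reads, 0)
  expect_equal(unname(prof$discarded["non_unique"]), 1L)
})

test_that("assignment is independent of read order", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  set.seed(5)
  picks <- sample(nrow(uniq), 200, replace = TRUE)
  reads <- paste0(fx$vp$reading_primer, uniq$sequence[picks])
  p1 <- assign_reads(reads, fx$vp, fx$lib)
  p2 <- assign_reads(rev(reads), fx$vp, fx$lib)
  expect_equal(p1$counts, p2$counts)
  expect_equal(p1$total_reads, 200)
})

test_that("FASTQ round trip preserves reads", {
  reads <- c("GATCAAAA", "TTTTGGGGCC")
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  expect_equal(read_fastq(fq), reads)
})

test_that("the single highest-coverage frag-end is removed deterministically", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  counts <- rep(0, nrow(uniq)); counts[c(3, 8, 15)] <- c(5, 3, 1)
  prof <- profile_from_counts(counts, fx$vp, fx$lib)
  filt <- remove_top_fragend(prof)
  expect_equal(filt$state, "filtered")
  expect_equal(nrow(filt$fragends), nrow(uniq) - 1L)
  expect_equal(filt$removed_fragend$id, uniq$id[3])
  expect_equal(filt$removed_fragend$count, 5)
  expect_equal(sum(filt$counts), 4)

  # tie broken by lowest genomic coordinate
  counts2 <- rep(0, nrow(uniq)); counts2[c(8, 3)] <- 5
  low <- which.min(uniq$pos[c(3, 8)])
  filt2 <- remove_top_fragend(profile_from_counts(counts2, fx$vp, fx$lib))
  expect_equal(filt2$removed_fragend$id, uniq$id[c(3, 8)][low])

  zeros <- profile_from_counts(rep(0, nrow(uniq)), fx$vp, fx$lib)
  expect_error(remove_top_fragend(zeros), "empty profile")
})

test_that("normalization scales the intrachromosomal sum to the target", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  cis <- which(uniq$chrom == "chr1")
  trans <- which(uniq$chrom == "chr2")
  counts <- rep(0, nrow(uniq))
  counts[cis[1:4]] <- c(10, 2, 3, 5)   # max (removed) + cis sum 10
  counts[trans[1]] <- 4
  prof <- remove_top_fragend(profile_from_counts(counts, fx$vp, fx$lib))
  norm <- normalize_profile(prof)
  expect_equal(norm$state, "normalized")
  expect_equal(norm$scale_factor, 1e5)
  got <- norm$counts[norm$counts > 0 & norm$fragends$chrom == "chr1"]
  expect_equal(sort(got), c(2e5, 3e5, 5e5))
  expect_equal(sum(norm$counts[norm$fragends$chrom == "chr1"]), 1e6,
               tolerance = 1e-6)
  # the trans frag-end is scaled by the same factor
  expect_equal(norm$counts[norm$fragends$id == uniq$id[trans[1]]], 4e5)

  # already at target -> identity
  counts3 <- rep(0, nrow(uniq))
  counts3[cis[1]] <- 2e6         # top, removed
  counts3[cis[2]] <- 1e6
  norm3 <- normalize_profile(remove_top_fragend(
    profile_from_counts(counts3, fx$vp, fx$lib)))
  expect_equal(norm3$scale_factor, 1)

  # no cis signal -> error
  counts4 <- rep(0, nrow(uniq))
  counts4[trans[1:2]] <- c(5, 3)
  expect_error(normalize_profile(remove_top_fragend(
    profile_from_counts(counts4, fx$vp, fx$lib))), "intrachromosomal")
})

test_that("running mean matches the naive sliding-window oracle", {
  set.seed(21)
  for (w in c(5L, 21L)) {
    x <- rexp(50)
    got <- running_mean_vec(x, w)
    expect_equal(got, oracle_running_mean(x, w), tolerance = 1e-12)
    # interior positions are plain full-window means
    h <- (w - 1L) / 2L
    for (i in (h + 1L):(50L - h)) {
      expect_equal(got[i], mean(x[(i - h):(i + h)]))
    }
  }
})

test_that("smoothing spreads an impulse over exactly window positions", {
  n <- 41
  values <- rep(0, n); values[21] <- 7
  prof <- make_normalized_profile(values, rep("chr1", n), seq_len(n) * 100L)
  sm <- running_mean(prof, window = 21L)
  expect_equal(sm$state, "smoothed")
  expect_equal(sum(sm$smoothed > 0), 21L)
  expect_equal(unique(sm$smoothed[sm$smoothed > 0]), 7 / 21)
})

test_that("smoothing is per-chromosome, linear, and mean-preserving inside", {
  set.seed(9)
  n <- 60
  chroms <- rep(c("chr1", "chr2"), each = n / 2)
  pos <- rep(seq_len(n / 2) * 50L, 2)
  x <- rexp(n); y <- rexp(n)
  px <- make_normalized_profile(x, chroms, pos)
  py <- make_normalized_profile(y, chroms, pos)
  pz <- make_normalized_profile(2 * x + 3 * y, chroms, pos)
  sx <- running_mean(px)$smoothed
  sy <- running_mean(py)$smoothed
  sz <- running_mean(pz)$smoothed
  expect_equal(sz, 2 * sx + 3 * sy, tolerance = 1e-12)
  # chromosomes smoothed independently
  expect_equal(sx[1:(n / 2)], oracle_running_mean(x[1:(n / 2)], 21L))
  expect_equal(sx[(n / 2 + 1):n], oracle_running_mean(x[(n / 2 + 1):n], 21L))
  # a constant profile is unchanged everywhere, shrunken edges included
  const <- make_normalized_profile(rep(4.2, 30), rep("chr1", 30),
                                   seq_len(30) * 10L)
  expect_equal(running_mean(const)$smoothed, rep(4.2, 30))
  # mass is conserved for signal >= 20 positions from both edges: every
  # value is then spread over exactly 21 full windows
  m <- 60
  x2 <- rep(0, m); x2[21:(m - 20)] <- rexp(m - 40)
  p2 <- make_normalized_profile(x2, rep("chr1", m), seq_len(m) * 10L)
  expect_equal(sum(running_mean(p2)$smoothed), sum(x2), tolerance = 1e-9)
})

test_that("state machine rejects out-of-order operations", {
  fx <- quant_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  counts <- seq_len(nrow(uniq))
  raw <- profile_from_counts(counts, fx$vp, fx$lib)
  expect_error(normalize_profile(raw), "filtered")
  expect_error(running_mean(raw), "normalized")
  norm <- normalize_profile(remove_top_fragend(raw))
  expect_error(running_mean(norm, window = 20L), "odd")
  expect_error(remove_top_fragend(norm), "raw")
})
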