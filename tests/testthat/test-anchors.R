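# Anchor construction, coverage sums and the pooled t test.

anchor_fixture <- function(seed = 13) {
  g <- random_genome(n_chrom = 2, len = 8000, seed = seed)
  lib <- build_fragend_library(g, restriction_scheme(extract_len = 20L))
  vp <- viewpoint("vp", "chr1", 4000L, "GTCCCAAGGGCACACTGATC")
  list(lib = lib, vp = vp)
}

test_that("anchors are half-open fixed-width intervals owning frag-ends", {
  fx <- anchor_fixture()
  a <- build_anchors(data.frame(chrom = "chr1", center = 4000L), fx$lib,
                     halfwidth = 1000L)
  expect_equal(a$start, 3000L)
  expect_equal(a$end, 5000L)
  expect_equal(a$end - a$start, 2L * 1000L)
  in_interval <- fx$lib$chrom == "chr1" & fx$lib$pos >= 3000 & fx$lib$pos < 5000
  expect_setequal(a$members[[1]], fx$lib$id[in_interval])

  # default halfwidth gives the 10 Kb anchor
  a10 <- build_anchors(data.frame(chrom = "chr1", center = 4000L), fx$lib)
  expect_equal(a10$end - a10$start, 10000L)

  expect_error(build_anchors(data.frame(chrom = "chr1", center = 99999L),
                             fx$lib), "outside")
  expect_error(build_anchors(data.frame(chrom = "chr1", center = 4000L),
                             fx$lib, halfwidth = 0L), "positive")
})

test_that("a frag-end exactly at center + halfwidth is excluded (half-open)", {
  # frag-ends at known positions: GATC at 1000, 2000, 3000
  g <- c(chrA = paste(c(strrep("A", 1000), "GATC", strrep("A", 996), "GATC",
                        strrep("A", 996), "GATC", strrep("A", 500)),
                      collapse = ""))
  lib <- build_fragend_library(g, restriction_scheme(extract_len = 10L))
  a <- build_anchors(data.frame(chrom = "chrA", center = 1500L), lib,
                     halfwidth = 500L)  # interval [1000, 2000)
  member_pos <- lib$pos[lib$id %in% a$members[[1]]]
  expect_true(all(member_pos >= 1000 & member_pos < 2000))
  expect_true(1000 %in% member_pos)    # left edge included
  expect_false(2000 %in% member_pos)   # right edge excluded
})

test_that("overlapping anchors share frag-ends; empty anchors are flagged", {
  fx <- anchor_fixture()
  a <- build_anchors(data.frame(chrom = "chr1", center = c(4000L, 4800L)),
                     fx$lib, halfwidth = 2500L)
  shared <- intersect(a$members[[1]], a$members[[2]])
  expect_gt(length(shared), 0L)

  # anchor over chr2 territory with no frag-ends near position 1 is empty
  g <- c(chrA = paste0(strrep("A", 5000), "GATC", strrep("A", 3000)))
  lib <- build_fragend_library(g, restriction_scheme(extract_len = 10L))
  e <- build_anchors(data.frame(chrom = "chrA", center = 500L), lib,
                     halfwidth = 400L)
  expect_true(e$empty)
  expect_equal(e$n_fragends, 0L)
})

test_that("anchor sums equal a brute-force filter-and-sum oracle", {
  fx <- anchor_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  set.seed(31)
  for (rep in 1:10) {
    counts <- rpois(nrow(uniq), 5)
    prof <- normalize_profile(remove_top_fragend(
      profile_from_counts(counts, fx$vp, fx$lib)))
    center <- sample(2000:6000, 1)
    hw <- sample(200:2000, 1)
    anchors <- build_anchors(data.frame(chrom = "chr1", center = center),
                             fx$lib, halfwidth = hw)
    got <- anchor_sums(list(prof), anchors)[1, 1]
    want <- oracle_anchor_sum(prof$counts, prof$fragends$chrom,
                              prof$fragends$pos, "chr1",
                              center - hw, center + hw)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("anchor sums are additive over a disjoint partition", {
  fx <- anchor_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  set.seed(8)
  prof <- normalize_profile(remove_top_fragend(
    profile_from_counts(rpois(nrow(uniq), 3), fx$vp, fx$lib)))
  whole <- build_anchors(data.frame(chrom = "chr1", center = 4000L), fx$lib,
                         halfwidth = 2000L)
  halves <- build_anchors(data.frame(chrom = "chr1",
                                     center = c(3000L, 5000L)), fx$lib,
                          halfwidth = 1000L)
  s <- anchor_sums(list(prof), whole)
  sh <- anchor_sums(list(prof), halves)
  expect_equal(s[1, 1], sh[1, 1] + sh[2, 1], tolerance = 1e-9)
})

test_that("anchor sums reject profiles in the wrong state", {
  fx <- anchor_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  raw <- profile_from_counts(rep(1, nrow(uniq)), fx$vp, fx$lib)
  anchors <- build_anchors(data.frame(chrom = "chr1", center = 4000L), fx$lib)
  expect_error(anchor_sums(list(raw), anchors), "normalized")
  sm <- running_mean(normalize_profile(remove_top_fragend(raw)))
  expect_error(anchor_sums(list(sm), anchors), "normalized")
})

test_that("pooled t test matches the closed form and stats::t.test", {
  set.seed(17)
  for (i in 1:200) {
    a <- rnorm(sample(2:6, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    b <- rnorm(sample(2:6, 1), mean = runif(1, -5, 5), sd = runif(1, 0.1, 3))
    got <- anchor_ttest(a, b)
    want <- oracle_pooled_t(a, b)
    expect_lt(abs(got$t_stat - want$t), 1e-10)
    expect_equal(got$p_value, want$p)
    expect_equal(got$dof, length(a) + length(b) - 2L)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("t test symmetry and degenerate cases", {
  a <- c(2, 4, 6); b <- c(1, 2, 3)
  fwd <- anchor_ttest(a, b)
  swp <- anchor_ttest(b, a)
  expect_equal(swp$t_stat, -fwd$t_stat)
  expect_equal(swp$p_value, fwd$p_value)

  same <- anchor_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  degen <- anchor_ttest(c(5, 5), c(5, 5))
  expect_equal(degen$note, "degenerate")
  expect_equal(degen$p_value, 1)

  inf <- anchor_ttest(c(5, 5), c(3, 3))
  expect_equal(inf$note, "infinite_t")
  expect_equal(inf$t_stat, Inf)
  expect_equal(inf$p_value, 0)

  expect_error(anchor_ttest(1, c(1, 2)), "at least 2")
})

test_that("welch option matches stats::t.test without pooling", {
  set.seed(23)
  a <- rnorm(5, sd = 3); b <- rnorm(4, sd = 0.3)
  got <- anchor_ttest(a, b, welch = TRUE)
  ref <- t.test(a, b)
  expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$dof, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("differential_contacts assembles the full results table", {
  fx <- anchor_fixture()
  uniq <- fx$lib[fx$lib$is_unique, ]
  set.seed(4)
  mkprof <- function() normalize_profile(remove_top_fragend(
    profile_from_counts(rpois(nrow(uniq), 4), fx$vp, fx$lib)))
  pa <- list(mkprof(), mkprof(), mkprof())
  pb <- list(mkprof(), mkprof(), mkprof())
  anchors <- build_anchors(data.frame(chrom = "chr1",
                                      center = c(2000L, 4000L, 6000L)),
                           fx$lib, halfwidth = 800L)
  res <- differential_contacts(pa, pb, anchors)
  expect_equal(nrow(res), 3L)
  expect_true(all(c("mean_a", "mean_b", "t_stat", "dof", "p_value", "note",
                    "p_bh") %in% names(res)))
  expect_equal(res$dof, rep(4, 3))
  expect_true(all(res$p_value >= 0 & res$p_value <= 1))
  expect_equal(res$p_bh, p.adjust(res$p_value, "BH"))
  # per-replicate sums present and consistent with the means
  sums_a <- as.matrix(res[, grep("^sum_a_", names(res))])
  expect_equal(unname(rowMeans(sums_a)), res$mean_a)
})
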