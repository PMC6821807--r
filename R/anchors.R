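# Anchor construction, per-anchor coverage sums, and the two-sample
# Student's t test of contacts between genotype groups.

#' Build fixed-width anchors around test positions
#'
#' An anchor is the half-open interval `[center - halfwidth,
#' center + halfwidth)` (10 Kb at the default halfwidth of 5,000 bp) owning
#' every frag-end whose boundary position falls inside it. Overlapping
#' anchors are permitted and share frag-ends; an anchor containing no
#' frag-end is kept but flagged empty.
#'
#' @param centers A data.frame with columns `chrom` and `center` (bp),
#'   optionally `name`, or a numeric vector of centers with `chrom` given
#'   separately via the `chrom` argument.
#' @param library A `fragend_library` (membership is evaluated over its
#'   rows; chromosome lengths from its `chrom_lengths` attribute bound the
#'   centers).
#' @param halfwidth Anchor half-width in bp, default 5,000.
#' @param chrom Chromosome name recycled over `centers` when `centers` is a
#'   bare numeric vector.
#' @return A data.frame of class `anchor_set`: `name`, `chrom`, `center`,
#'   `start`, `end`, `n_fragends`, `empty`, and a list-column `members` of
#'   member frag-end ids.
#' @export
build_anchors <- function(centers, library, halfwidth = 5000L, chrom = NULL) {
  if (is.numeric(centers)) {
    if (is.null(chrom)) stop("'chrom' required when 'centers' is a bare vector")
    centers <- data.frame(chrom = chrom, center = centers)
  }
  stopifnot(is.data.frame(centers), all(c("chrom", "center") %in% names(centers)))
  if (!"name" %in% names(centers)) {
    centers$name <- paste0("anchor_", centers$chrom, "_", centers$center)
  }
  halfwidth <- as.integer(halfwidth)
  if (halfwidth <= 0L) stop("'halfwidth' must be positive")
  lens <- attr(library, "chrom_lengths")
  if (!is.null(lens)) {
    for (i in seq_len(nrow(centers))) {
      cl <- lens[centers$chrom[i]]
      if (is.na(cl) || centers$center[i] < 0 || centers$center[i] >= cl) {
        stop("anchor center ", centers$chrom[i], ":", centers$center[i],
             " lies outside the chromosome")
      }
    }
  }
  out <- data.frame(
    name = centers$name,
    chrom = centers$chrom,
    center = as.integer(centers$center),
    start = as.integer(centers$center) - halfwidth,
    end = as.integer(centers$center) + halfwidth
  )
  out$members <- lapply(seq_len(nrow(out)), function(i) {
    hit <- library$chrom == out$chrom[i] &
      library$pos >= out$start[i] & library$pos < out$end[i]
    library$id[hit]
  })
  out$n_fragends <- lengths(out$members)
  out$empty <- out$n_fragends == 0L
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Sum normalized coverage over anchors, per replicate
#'
#' For each anchor and each normalized profile, sums the normalized values
#' of the anchor's member frag-ends. Sums are taken on normalized,
#' unsmoothed coverage: the running mean is for profile display only.
#' An empty anchor sums to 0.
#'
#' @param profiles A list of `coverage_profile` objects in state
#'   `"normalized"` (one per replicate), built on the same frag-end library.
#' @param anchors An `anchor_set` from [build_anchors()].
#' @return A numeric matrix, anchors x replicates, with anchor names as row
#'   names and profile names (or `rep1..repN`) as column names.
#' @export
anchor_sums <- function(profiles, anchors) {
  if (inherits(profiles, "coverage_profile")) profiles <- list(profiles)
  for (p in profiles) check_state(p, "normalized")
  if (is.null(names(profiles)) || any(names(profiles) == "")) {
    names(profiles) <- paste0("rep", seq_along(profiles))
  }
  out <- matrix(0, nrow = nrow(anchors), ncol = length(profiles),
                dimnames = list(anchors$name, names(profiles)))
  for (j in seq_along(profiles)) {
    v <- profiles[[j]]$counts
    names(v) <- profiles[[j]]$fragends$id
    for (i in seq_len(nrow(anchors))) {
      ids <- anchors$members[[i]]
      out[i, j] <- sum(v[ids[ids %in% names(v)]])
    }
  }
  out
}

#' Unpaired Student's t test (pooled variance)
#'
#' The two-sample t statistic with pooled variance and
#' `n_a + n_b - 2` degrees of freedom; the two-sided p-value comes from the
#' t distribution. Degenerate inputs are flagged rather than producing NaN:
#' zero pooled variance with equal means gives `t = 0, p = 1`
#' (note `"degenerate"`), zero pooled variance with unequal means gives an
#' infinite t and `p = 0` (note `"infinite_t"`). Welch's unequal-variance
#' test is available behind `welch = TRUE` but the pooled form is the
#' default.
#'
#' @param sums_a,sums_b Numeric vectors of per-replicate values for the two
#'   groups; each must have at least 2 values.
#' @param welch Use Welch's t instead of the pooled form (default FALSE).
#' @return A list of class `anchor_ttest`: `mean_a`, `mean_b`, `t_stat`,
#'   `dof`, `p_value`, `note` (`""` when regular).
#' @export
anchor_ttest <- function(sums_a, sums_b, welch = FALSE) {
  sums_a <- as.numeric(sums_a)
  sums_b <- as.numeric(sums_b)
  n_a <- length(sums_a)
  n_b <- length(sums_b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 replicates")
  m_a <- mean(sums_a)
  m_b <- mean(sums_b)
  ss_a <- sum((sums_a - m_a)^2)
  ss_b <- sum((sums_b - m_b)^2)
  if (welch) {
    va <- ss_a / (n_a - 1L); vb <- ss_b / (n_b - 1L)
    se2 <- va / n_a + vb / n_b
    dof <- if (se2 > 0) se2^2 / ((va / n_a)^2 / (n_a - 1L) +
                                 (vb / n_b)^2 / (n_b - 1L)) else n_a + n_b - 2L
  } else {
    dof <- n_a + n_b - 2L
    se2 <- (ss_a + ss_b) / dof * (1 / n_a + 1 / n_b)
  }
  if (se2 == 0) {
    if (m_a == m_b) {
      res <- list(mean_a = m_a, mean_b = m_b, t_stat = 0, dof = dof,
                  p_value = 1, note = "degenerate")
    } else {
      res <- list(mean_a = m_a, mean_b = m_b,
                  t_stat = sign(m_a - m_b) * Inf, dof = dof,
                  p_value = 0, note = "infinite_t")
    }
  } else {
    t_stat <- (m_a - m_b) / sqrt(se2)
    res <- list(mean_a = m_a, mean_b = m_b, t_stat = t_stat, dof = dof,
                p_value = 2 * stats::pt(-abs(t_stat), dof), note = "")
  }
  class(res) <- "anchor_ttest"
  res
}

#' @export
print.anchor_ttest <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g (mean A %.4g vs mean B %.4g)%s\n",
              x$t_stat, x$dof, x$p_value, x$mean_a, x$mean_b,
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Differential contact test over anchors
#'
#' Runs [anchor_sums()] on both genotype groups and [anchor_ttest()] per
#' anchor, returning the full results table. No multiple-testing correction
#' is applied to the reported p-values (raw p, matching the test's use on a
#' handful of pre-specified anchors); a Benjamini-Hochberg adjusted column
#' `p_bh` is appended for convenience and clearly labelled as such.
#'
#' @param profiles_a,profiles_b Lists of normalized `coverage_profile`
#'   objects for groups A and B (e.g. wildtype and mutant replicates).
#' @param anchors An `anchor_set`.
#' @param welch Passed to [anchor_ttest()].
#' @return A data.frame with one row per anchor: interval, `n_fragends`,
#'   per-replicate sums (`sum_a_*`, `sum_b_*`), `mean_a`, `mean_b`,
#'   `ratio_b_over_a`, `t_stat`, `dof`, `p_value`, `note`, `p_bh`.
#' @export
differential_contacts <- function(profiles_a, profiles_b, anchors,
                                  welch = FALSE) {
  sa <- anchor_sums(profiles_a, anchors)
  sb <- anchor_sums(profiles_b, anchors)
  tests <- lapply(seq_len(nrow(anchors)),
                  function(i) anchor_ttest(sa[i, ], sb[i, ], welch = welch))
  res <- data.frame(
    anchor = anchors$name,
    chrom = anchors$chrom,
    start = anchors$start,
    end = anchors$end,
    n_fragends = anchors$n_fragends
  )
  colnames(sa) <- paste0("sum_a_", colnames(sa))
  colnames(sb) <- paste0("sum_b_", colnames(sb))
  res <- cbind(res, as.data.frame(sa), as.data.frame(sb))
  res$mean_a <- vapply(tests, `[[`, numeric(1), "mean_a")
  res$mean_b <- vapply(tests, `[[`, numeric(1), "mean_b")
  res$ratio_b_over_a <- ifelse(res$mean_a > 0, res$mean_b / res$mean_a, NA_real_)
  res$t_stat <- vapply(tests, `[[`, numeric(1), "t_stat")
  res$dof <- vapply(tests, `[[`, numeric(1), "dof")
  res$p_value <- vapply(tests, `[[`, numeric(1), "p_value")
  res$note <- vapply(tests, `[[`, character(1), "note")
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  rownames(res) <- NULL
  res
}

#' Write an anchor results table as TSV
#'
#' @param results Table from [differential_contacts()].
#' @param path Output path.
#' @export
write_anchor_results <- function(results, path) {
  num <- vapply(results, is.numeric, logical(1))
  out <- results
  out[num] <- lapply(out[num], function(x) format(x, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
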