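# Reference-gene-normalized expression quantities and the two-allele
# activity model for enhancer-deletion expression changes.

#' Normalize expression quantities to reference genes
#'
#' Divides each gene's quantity, per sample, by the geometric mean of that
#' sample's reference-gene quantities (the standard RT-qPCR normalization
#' to e.g. the geomean of cTnI and Hprt). Quantities are LinRegPCR-style
#' relative start concentrations; normalization is invariant to a uniform
#' per-sample scale factor, which models loading differences.
#'
#' @param table Long-format data.frame with columns `gene`, `sample`,
#'   `quantity` (non-negative) and optionally `genotype`, `tissue`.
#' @param reference_genes Character vector of reference gene names; every
#'   sample must carry each of them with quantity > 0.
#' @return The table with an added `normalized` column.
#' @export
normalize_expression <- function(table, reference_genes) {
  stopifnot(is.data.frame(table),
            all(c("gene", "sample", "quantity") %in% names(table)))
  if (length(reference_genes) == 0L) stop("no reference genes given")
  if (any(table$quantity < 0)) stop("negative expression quantity")
  geo <- vapply(split(table, table$sample), function(d) {
    q <- d$quantity[match(reference_genes, d$gene)]
    if (anyNA(q) || any(q <= 0)) {
      stop("sample '", d$sample[1],
           "' is missing a positive quantity for a reference gene")
    }
    exp(mean(log(q)))
  }, numeric(1))
  table$normalized <- table$quantity / geo[as.character(table$sample)]
  table
}

#' Fold change of a gene between two sample groups
#'
#' Mean of the normalized quantities in the test group divided by the mean
#' in the reference group (group summary by arithmetic mean, as in
#' mean-plus-SEM bar plots).
#'
#' @param normalized Table from [normalize_expression()].
#' @param group_ref,group_test Character vectors of sample names.
#' @param gene Gene to evaluate.
#' @return The fold change (test / reference); `NA` with a warning when the
#'   reference mean is zero.
#' @export
fold_change <- function(normalized, group_ref, group_test, gene) {
  stopifnot("normalized" %in% names(normalized))
  if (length(group_ref) == 0L || length(group_test) == 0L) {
    stop("both sample groups must be non-empty")
  }
  g <- normalized[normalized$gene == gene, , drop = FALSE]
  ref <- g$normalized[g$sample %in% group_ref]
  test <- g$normalized[g$sample %in% group_test]
  if (length(ref) == 0L || length(test) == 0L) {
    stop("gene '", gene, "' not measured in one of the groups")
  }
  m_ref <- mean(ref)
  if (m_ref == 0) {
    warning("reference group mean is zero for gene '", gene, "'")
    return(NA_real_)
  }
  mean(test) / m_ref
}

#' Two-allele activity model of enhancer-deletion expression
#'
#' Models total transcript output as the sum of two allele activities, with
#' the wildtype per-allele output defined as 1, so the `(1, 1)` genotype is
#' the reference. A heterozygous deletion that fully silences its allele has
#' activities `(1, 0)`: total output drops by 50% and the silenced allele
#' contributes no transcript, so a diagnostic sequence variant on that
#' allele vanishes from the cDNA — the monoallelic expression signature.
#'
#' @param activities Numeric pair of non-negative per-allele transcriptional
#'   outputs (wildtype allele = 1).
#' @return A list of class `allele_model_prediction`:
#'   `percent_reduction` (100 x (1 - (a1 + a2) / 2) versus the `(1, 1)`
#'   wildtype), `allele_fractions` (each allele's share of total
#'   transcript), `silenced_allele_fraction` (share of the lower-activity
#'   allele), `note` (`"both_silent"` when both activities are 0, in which
#'   case fractions are undefined).
#' @export
monoallelic_prediction <- function(activities) {
  activities <- as.numeric(activities)
  if (length(activities) != 2L || anyNA(activities) || any(activities < 0)) {
    stop("'activities' must be two non-negative numbers")
  }
  total <- sum(activities)
  reduction <- 100 * (1 - total / 2)
  if (total == 0) {
    res <- list(percent_reduction = 100,
                allele_fractions = c(NA_real_, NA_real_),
                silenced_allele_fraction = NA_real_,
                note = "both_silent")
  } else {
    fr <- activities / total
    res <- list(percent_reduction = reduction,
                allele_fractions = fr,
                silenced_allele_fraction = fr[which.min(activities)],
                note = "")
  }
  class(res) <- "allele_model_prediction"
  res
}

#' @export
print.allele_model_prediction <- function(x, ...) {
  cat(sprintf("allele model: %.3g%% reduction vs wildtype", x$percent_reduction))
  if (!nzchar(x$note)) {
    cat(sprintf("; allele fractions %.3g / %.3g", x$allele_fractions[1],
                x$allele_fractions[2]))
  } else {
    cat(" [", x$note, "]", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Expression fold change plus unpaired t test between two genotypes
#'
#' Convenience wrapper: normalizes, computes the fold change for each
#' requested gene and tests the group difference of normalized quantities
#' with the same pooled-variance Student's t kernel used for anchor
#' contacts ([anchor_ttest()]).
#'
#' @param table Long-format expression table (see [normalize_expression()]).
#' @param reference_genes Reference genes for normalization.
#' @param group_ref,group_test Sample name vectors.
#' @param genes Genes to test; defaults to all non-reference genes.
#' @return Data.frame with `gene`, `fold_change`, `mean_ref`, `mean_test`,
#'   `t_stat`, `dof`, `p_value`, `note`.
#' @export
expression_test <- function(table, reference_genes, group_ref, group_test,
                            genes = NULL) {
  norm <- normalize_expression(table, reference_genes)
  if (is.null(genes)) {
    genes <- setdiff(unique(norm$gene), reference_genes)
  }
  rows <- lapply(genes, function(g) {
    d <- norm[norm$gene == g, , drop = FALSE]
    ref <- d$normalized[d$sample %in% group_ref]
    test <- d$normalized[d$sample %in% group_test]
    tt <- anchor_ttest(ref, test)
    data.frame(gene = g, fold_change = mean(test) / mean(ref),
               mean_ref = tt$mean_a, mean_test = tt$mean_b,
               t_stat = tt$t_stat, dof = tt$dof, p_value = tt$p_value,
               note = tt$note)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
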