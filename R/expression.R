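# Differential expression between anchor-loss and diploid samples, p-value
# adjustment, pathway-input selection and hypergeometric over-representation.

#' Standardize an expression matrix gene-wise
#'
#' Each gene (row) is centered and scaled across samples with the sample
#' standard deviation (denominator n - 1). Genes with zero variance cannot
#' be standardized: they are dropped and reported via the `dropped`
#' attribute.
#'
#' @param expr numeric matrix, genes x samples.
#' @return z-scored matrix (`scale_tag = "zscore"`), attribute `dropped`.
#' @export
zscore_by_gene <- function(expr) {
  if (ncol(expr) < 2) stop("need >= 2 samples to standardize")
  sds <- apply(expr, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (any(drop)) bs_log("dropped ", sum(drop), " zero-variance gene(s)")
  z <- t(scale(t(expr[!drop, , drop = FALSE])))
  attr(z, "scale_tag") <- "zscore"
  attr(z, "dropped") <- rownames(expr)[drop]
  z
}

#' Differential expression between two sample groups
#'
#' Per gene: effect = median(value | loss) - median(value | neutral), and a
#' two-sided independent-samples rank-sum (Mann-Whitney) p value, adjusted
#' across all tested genes. Significance is at adjusted p < 0.05.
#'
#' The rank-sum test is used for both the gene-expression mode (with
#' Bonferroni adjustment) and the protein mode (with BH), which reuses the
#' identical machinery.
#'
#' @param expr numeric matrix, genes x samples (typically z-scored with
#'   [zscore_by_gene()]).
#' @param groups named vector of `"loss"` / `"neutral"` labels; samples not
#'   named here are ignored.
#' @param adjust `"bonferroni"` or `"bh"`.
#' @return data.frame `gene_id`, `delta_median`, `p_value`, `p_adjusted`,
#'   `adjust_method`, `significant`, sorted by adjusted p.
#' @export
differential_expression <- function(expr, groups,
                                    adjust = c("bonferroni", "bh")) {
  adjust <- match.arg(adjust)
  groups <- groups[names(groups) %in% colnames(expr)]
  loss_ids <- names(groups)[groups == "loss"]
  neut_ids <- names(groups)[groups == "neutral"]
  if (length(loss_ids) < 2 || length(neut_ids) < 2)
    stop("both groups need >= 2 samples")
  xl <- expr[, loss_ids, drop = FALSE]
  xn <- expr[, neut_ids, drop = FALSE]
  eff <- apply(xl, 1, stats::median) - apply(xn, 1, stats::median)
  p <- vapply(seq_len(nrow(expr)), function(i)
    rank_sum_p(xl[i, ], xn[i, ]), 1.0)
  padj <- adjust_pvalues(p, method = adjust)
  out <- data.frame(gene_id = rownames(expr), delta_median = eff,
                    p_value = p, p_adjusted = padj, adjust_method = adjust,
                    significant = padj < 0.05, stringsAsFactors = FALSE)
  out <- out[order(out$p_adjusted, -abs(out$delta_median)), ]
  rownames(out) <- NULL
  out
}

# Two-sided rank-sum p: exact when small and tie-free, tie-corrected normal
# approximation otherwise.
rank_sum_p <- function(x, y, alternative = "two.sided") {
  n <- length(x) + length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n <= 20 && !ties
  p <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                           exact = exact,
                                           correct = FALSE)$p.value)
  if (is.na(p)) 1 else p  # fully tied data carry no evidence
}

#' Adjust p values (Bonferroni or Benjamini-Hochberg)
#'
#' Bonferroni: `min(1, m * p)`. BH: step-up with enforced monotonicity.
#'
#' @param p numeric vector in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return adjusted p values, same order as input.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1 | is.na(p))) stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Select the differential-expression input for pathway analysis
#'
#' Ranks genes by adjusted p ascending (ties by |effect| descending),
#' removes downregulated genes located on the anchor's chromosome arm
#' (their signal is explained by the copy-number loss itself), and returns
#' the top `k` survivors; upregulated genes on that arm are retained.
#'
#' @param results data.frame from [differential_expression()].
#' @param k number of genes to keep (default 50).
#' @param gene_arms named character vector, gene id -> chromosome arm
#'   (e.g. `"13q"`).
#' @param anchor_arm arm to exclude downregulated genes from.
#' @return character vector of gene ids (length <= k, with a warning when
#'   fewer survive).
#' @export
select_pathway_input <- function(results, k = 50, gene_arms,
                                 anchor_arm = "13q") {
  if (k <= 0) stop("k must be positive")
  r <- results[order(results$p_adjusted, -abs(results$delta_median)), ]
  arm <- unname(gene_arms[r$gene_id])
  drop <- r$delta_median < 0 & !is.na(arm) & arm == anchor_arm
  surv <- r$gene_id[!drop]
  if (length(surv) < k)
    warning("only ", length(surv), " genes survive the arm exclusion")
  utils::head(surv, k)
}

#' Hypergeometric over-representation analysis over GMT gene sets
#'
#' For each set S (intersected with the universe) and query list L, the
#' p value is the upper tail of the hypergeometric distribution of
#' |L intersect S|; BH adjustment is applied across sets. Sets disjoint from
#' the universe are skipped and reported.
#'
#' @param genes character vector, the query list (intersected with the
#'   universe; genes outside it are dropped with a log line).
#' @param gene_sets named list of character vectors ([read_gene_sets()]).
#' @param universe character vector of all testable gene ids.
#' @return data.frame `set`, `set_size`, `overlap`, `p_value`, `q_value`;
#'   attribute `skipped` lists sets with no universe member.
#' @export
ora_hypergeometric <- function(genes, gene_sets, universe) {
  if (length(universe) == 0) stop("empty universe")
  universe <- unique(universe)
  outside <- setdiff(genes, universe)
  if (length(outside)) bs_log("dropped ", length(outside),
                              " query genes outside the universe")
  genes <- intersect(unique(genes), universe)
  sets <- lapply(gene_sets, intersect, universe)
  skipped <- names(sets)[vapply(sets, length, 1L) == 0]
  sets <- sets[vapply(sets, length, 1L) > 0]
  if (length(sets) == 0) {
    out <- data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p_value = numeric(),
                      q_value = numeric())
    attr(out, "skipped") <- skipped
    return(out)
  }
  N <- length(universe); nq <- length(genes)
  res <- t(vapply(sets, function(s) {
    ov <- length(intersect(genes, s))
    p <- stats::phyper(ov - 1, length(s), N - length(s), nq,
                       lower.tail = FALSE)
    c(set_size = length(s), overlap = ov, p_value = min(p, 1))
  }, c(set_size = 0, overlap = 0, p_value = 0)))
  out <- data.frame(set = names(sets), res, stringsAsFactors = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Chromosome arm of each gene
#'
#' Derives a gene -> arm map (e.g. `"13q"`) from the band assignment: the
#' arm is the chromosome plus the arm letter of the containing band.
#'
#' @param annotation a [genome_annotation()].
#' @return named character vector, gene id -> arm.
#' @export
gene_arms <- function(annotation) {
  asg <- assign_genes_to_bands(annotation)$assignment
  chrom_len <- nchar(sub("^([0-9XYM]+)[pq].*$", "\\1", asg$band_name))
  arm <- substr(asg$band_name, 1, chrom_len + 1)
  stats::setNames(arm, asg$gene_id)
}
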