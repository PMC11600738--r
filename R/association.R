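# Co-occurrence / mutual-exclusivity screening against a binary anchor
# event (cytoband loss) with Fisher exact tests.

#' Binarize band statuses into an anchor event vector
#'
#' 1 = loss (per `loss_def`), 0 = neutral. Samples with gain, amplification,
#' ambiguous or missing status are excluded from two-group contrasts and
#' listed, following the loss-vs-diploid comparison design.
#'
#' @param statuses named character vector of band statuses per sample.
#' @param loss_def statuses counted as the event.
#' @return named 0/1 integer vector with attribute `excluded`.
#' @export
binary_anchor <- function(statuses, loss_def = c("loss", "deep_loss")) {
  is_loss <- statuses %in% loss_def
  is_neut <- statuses == "neutral"
  keep <- is_loss | is_neut
  if (!any(is_loss) || !any(is_neut))
    stop("degenerate anchor: need at least one loss and one neutral sample")
  out <- as.integer(is_loss[keep])
  names(out) <- names(statuses)[keep]
  attr(out, "excluded") <- names(statuses)[!keep]
  out
}

#' Fisher exact association of a binary feature with the anchor
#'
#' Builds the 2x2 table (a = anchor+/feature+, b = anchor+/feature-,
#' c = anchor-/feature+, d = anchor-/feature-), computes the two-sided
#' Fisher exact p, the sample odds ratio `ad/bc` (with the
#' Haldane--Anscombe +0.5 applied to every cell iff any cell is zero; the
#' exact p always uses the raw counts), `direction = log2(OR)` and
#' `score = -log10(p) * direction`. At p = 1 the score is defined as 0.
#'
#' @param anchor 0/1 vector.
#' @param feature 0/1 vector, same length and order.
#' @param alpha significance level for the call (default 0.05).
#' @param feature_id label carried into the result.
#' @return one-row data.frame with counts, `odds_ratio`, `p_value`,
#'   `direction`, `score`, `call`.
#' @export
fisher_association <- function(anchor, feature, alpha = 0.05,
                               feature_id = NA_character_) {
  if (length(anchor) != length(feature))
    stop("anchor and feature vectors differ in length")
  stopifnot(all(anchor %in% 0:1), all(feature %in% 0:1))
  a <- sum(anchor == 1 & feature == 1)
  b <- sum(anchor == 1 & feature == 0)
  c_ <- sum(anchor == 0 & feature == 1)
  d <- sum(anchor == 0 & feature == 0)
  assoc_from_counts(a, b, c_, d, alpha = alpha, feature_id = feature_id)
}

assoc_from_counts <- function(a, b, c_, d, alpha = 0.05,
                              feature_id = NA_character_) {
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  p <- min(p, 1)
  or <- if (any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else (a * d) / (b * c_)
  direction <- log2(or)
  score <- if (p >= 1 || direction == 0) 0 else -log10(p) * direction
  call <- if (p < alpha && direction > 0) "co_occurring"
  else if (p < alpha && direction < 0) "mutually_exclusive"
  else "not_significant"
  data.frame(feature_id = feature_id, a = a, b = b, c = c_, d = d,
             odds_ratio = or, p_value = p, direction = direction,
             score = score, call = call, stringsAsFactors = FALSE)
}

#' Screen a feature set against the anchor
#'
#' Features with prevalence not exceeding `min_prevalence` among the tested
#' samples are dropped before testing (mirroring the "mutation frequency
#' greater than 2%" rule). Results are sorted by |score| descending. For
#' copy-number features, bands on the anchor's chromosome arm can be flagged
#' (linkage/adjacency caveat) via `feature_arms`; they are flagged, never
#' removed. No multiple-testing correction is applied by default (raw
#' p < alpha, as in the screen this reimplements); `adjust = "bh"` switches
#' the call to BH-adjusted q values.
#'
#' @param anchor named 0/1 vector from [binary_anchor()].
#' @param features 0/1 matrix, samples in rows (named), features in columns.
#' @param min_prevalence prevalence threshold (default 0.02, strict).
#' @param alpha significance level.
#' @param adjust `"none"` or `"bh"`.
#' @param feature_arms optional named vector mapping feature id to
#'   chromosome arm, used with `anchor_arm` to set the `same_arm` flag.
#' @param anchor_arm chromosome arm of the anchor, e.g. `"13q"`.
#' @return data.frame of association results (one row per tested feature).
#' @export
screen_features <- function(anchor, features, min_prevalence = 0.02,
                            alpha = 0.05, adjust = c("none", "bh"),
                            feature_arms = NULL, anchor_arm = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(min_prevalence >= 0, min_prevalence < 1)
  common <- intersect(names(anchor), rownames(features))
  if (length(common) == 0) stop("no samples shared between anchor and features")
  anc <- anchor[common]
  feats <- features[common, , drop = FALSE]
  prev <- colMeans(feats)
  tested <- colnames(feats)[prev > min_prevalence]
  if (length(tested) == 0) {
    warning("no feature passes the prevalence filter")
    return(data.frame())
  }
  res <- do.call(rbind, lapply(tested, function(f)
    fisher_association(anc, feats[, f], alpha = alpha, feature_id = f)))
  res$prevalence <- prev[tested]
  if (adjust == "bh") {
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    res$call <- ifelse(res$q_value < alpha & res$direction > 0, "co_occurring",
                ifelse(res$q_value < alpha & res$direction < 0,
                       "mutually_exclusive", "not_significant"))
  }
  if (!is.null(feature_arms) && !is.null(anchor_arm))
    res$same_arm <- unname(feature_arms[res$feature_id] == anchor_arm)
  res <- res[order(-abs(res$score)), ]
  rownames(res) <- NULL
  res
}

#' Features with a consistent call across two cohorts
#'
#' A feature is consistent iff it carries the same call, and that call is
#' `co_occurring` or `mutually_exclusive`, in both cohorts.
#'
#' @param results_a,results_b screen results from [screen_features()].
#' @return data.frame `feature_id`, `call`, `score_a`, `score_b`.
#' @export
cross_cohort_consistency <- function(results_a, results_b) {
  if (nrow(results_a) == 0 || nrow(results_b) == 0 ||
      length(intersect(results_a$feature_id, results_b$feature_id)) == 0) {
    warning("no shared features between cohorts")
    return(data.frame(feature_id = character(), call = character(),
                      score_a = numeric(), score_b = numeric()))
  }
  m <- merge(results_a[c("feature_id", "call", "score")],
             results_b[c("feature_id", "call", "score")],
             by = "feature_id", suffixes = c("_a", "_b"))
  keep <- m$call_a == m$call_b &
    m$call_a %in% c("co_occurring", "mutually_exclusive")
  out <- data.frame(feature_id = m$feature_id[keep], call = m$call_a[keep],
                    score_a = m$score_a[keep], score_b = m$score_b[keep],
                    stringsAsFactors = FALSE)
  out[order(-abs(out$score_a)), , drop = FALSE]
}

#' Run the association screen independently per clinical stratum
#'
#' Strata in which the anchor has a single class are reported as untestable,
#' not errored.
#'
#' @param anchor named 0/1 vector.
#' @param features 0/1 feature matrix (samples x features).
#' @param clinical clinical table with `sample_id` and the grouping column.
#' @param grouping name of the clinical column defining strata.
#' @param ... passed to [screen_features()].
#' @return list with `results` (named list of data.frames) and `untestable`
#'   (character vector of stratum labels).
#' @export
stratified_screen <- function(anchor, features, clinical, grouping, ...) {
  grp <- clinical[[grouping]]
  names(grp) <- clinical$sample_id
  grp <- grp[names(anchor)]
  res <- list(); untestable <- character()
  for (lev in sort(unique(grp[!is.na(grp)]))) {
    ids <- names(grp)[!is.na(grp) & grp == lev]
    anc <- anchor[ids]
    if (length(unique(anc)) < 2) {
      untestable <- c(untestable, lev)
      next
    }
    res[[lev]] <- screen_features(anc, features, ...)
  }
  list(results = res, untestable = untestable)
}
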