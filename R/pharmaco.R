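# Pharmacogenomic screening of binary genomic features against drug
# log10 IC50 response: Glass' delta, point-biserial r, Mann-Whitney tests,
# per-screen BH FDR, elastic-net ranking, and an anchor-only mode.

#' Glass' delta effect sizes for a two-group IC50 comparison
#'
#' `mean_diff = mean(pos) - mean(neg)`; `delta_pos` and `delta_neg` divide
#' |mean_diff| by the sample standard deviation of the respective group.
#' Groups with fewer than two values or zero spread are flagged untestable
#' rather than raising an error.
#'
#' @param pos values for feature-positive lines (log10 IC50).
#' @param neg values for feature-negative lines.
#' @return list `mean_diff`, `delta_pos`, `delta_neg`, `untestable`.
#' @export
glass_delta <- function(pos, neg) {
  if (length(pos) < 2 || length(neg) < 2)
    return(list(mean_diff = NA_real_, delta_pos = NA_real_,
                delta_neg = NA_real_, untestable = TRUE))
  sp <- stats::sd(pos); sn <- stats::sd(neg)
  md <- mean(pos) - mean(neg)
  if (sp == 0 || sn == 0)
    return(list(mean_diff = md, delta_pos = NA_real_, delta_neg = NA_real_,
                untestable = TRUE))
  list(mean_diff = md, delta_pos = abs(md) / sp, delta_neg = abs(md) / sn,
       untestable = FALSE)
}

#' Point-biserial correlation with Fisher-z confidence interval
#'
#' r is the Pearson correlation between the 0/1 group indicator and the
#' values; the 95% CI uses the Fisher z transform with standard error
#' `1/sqrt(n - 3)` (undefined for n <= 3, r still returned). The magnitude
#' label uses the |r| boundaries 0.10 / 0.24 / 0.37 between negligible,
#' small, medium and large.
#'
#' @param indicator 0/1 vector.
#' @param values numeric vector, same length.
#' @return list `r`, `ci_low`, `ci_high`, `magnitude`.
#' @export
point_biserial <- function(indicator, values) {
  stopifnot(length(indicator) == length(values),
            all(indicator %in% 0:1))
  if (length(unique(indicator)) < 2 || stats::sd(values) == 0)
    return(list(r = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                magnitude = NA_character_))
  n <- length(values)
  r <- stats::cor(indicator, values)
  if (n > 3) {
    z <- atanh(r); se <- 1 / sqrt(n - 3)
    ci <- tanh(z + c(-1, 1) * stats::qnorm(0.975) * se)
  } else ci <- c(NA_real_, NA_real_)
  list(r = r, ci_low = ci[1], ci_high = ci[2],
       magnitude = r_magnitude(r))
}

r_magnitude <- function(r) {
  a <- abs(r)
  if (a < 0.10) "negligible" else if (a < 0.24) "small"
  else if (a < 0.37) "medium" else "large"
}

#' Mann-Whitney U test between two groups
#'
#' Exact for combined n <= 20 without ties; tie-corrected normal
#' approximation otherwise.
#'
#' @param pos,neg numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"` (positive
#'   group vs negative group).
#' @return p value.
#' @export
mw_group_test <- function(pos, neg,
                          alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  alt <- sub("two_sided", "two.sided", alternative)
  rank_sum_p(pos, neg, alternative = alt)
}

#' Elastic-net ranking of features against one drug's response
#'
#' Standardized features, penalty mixing alpha (default 0.5), penalty
#' chosen by k-fold cross-validation at the 1-SE rule. Nonzero coefficients
#' mark candidate pharmacogenomic interactions. The CV fold split consumes
#' the RNG stream; seed before calling for reproducibility.
#'
#' @param response numeric vector of log10 IC50, named by cell line.
#' @param features 0/1 matrix, cell lines x features.
#' @param mixing elastic-net mixing parameter in \[0, 1\].
#' @param folds number of CV folds (default 10).
#' @return named numeric vector of coefficients at the 1-SE penalty.
#' @export
elastic_net_screen <- function(response, features, mixing = 0.5, folds = 10) {
  common <- intersect(names(response), rownames(features))
  if (length(common) < 2 * folds)
    stop("need >= ", 2 * folds, " cell lines with response")
  y <- response[common]
  x <- features[common, , drop = FALSE]
  coefs <- stats::setNames(rep(0, ncol(x)), colnames(x))
  if (stats::sd(y) == 0) {
    warning("constant response; all coefficients zero")
    return(coefs)
  }
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, `.pad` = 0)
  fit <- glmnet::cv.glmnet(x, y, alpha = mixing, nfolds = folds,
                           standardize = TRUE)
  b <- as.numeric(stats::coef(fit, s = "lambda.1se"))[-1]
  names(b) <- colnames(x)
  if (padded) b <- b[names(b) != ".pad"]
  b
}

pharmaco_one <- function(vals, ind, min_group) {
  n_pos <- sum(ind == 1); n_neg <- sum(ind == 0)
  gd <- glass_delta(vals[ind == 1], vals[ind == 0])
  untestable <- n_pos < min_group || n_neg < min_group || gd$untestable
  pb <- point_biserial(ind, vals)
  p <- if (untestable) NA_real_ else mw_group_test(vals[ind == 1],
                                                   vals[ind == 0])
  data.frame(n_pos = n_pos, n_neg = n_neg, mean_diff = gd$mean_diff,
             glass_delta_pos = gd$delta_pos, glass_delta_neg = gd$delta_neg,
             mw_p = p, r_pb = pb$r, r_ci_low = pb$ci_low,
             r_ci_high = pb$ci_high,
             magnitude = if (is.null(pb$magnitude)) NA_character_ else pb$magnitude,
             untestable = untestable, stringsAsFactors = FALSE)
}

#' Genome-wide feature x drug interaction screen
#'
#' For every (feature, drug, screen) triple with at least `min_group` cell
#' lines per genotype class: Glass' delta (both group denominators),
#' Mann-Whitney p, point-biserial r with CI and magnitude, and BH q across
#' all tested triples (per screen by default, since IC50 scales differ
#' across screens; `pool_screens = TRUE` pools). A triple is a hit iff
#' `mw_p < p_cutoff` and `q < fdr_cutoff` and the smaller of the two Glass'
#' deltas exceeds `delta_cutoff`. Direction is `sensitivity` when the
#' feature-positive group has lower IC50.
#'
#' @param responses drug-response data.frame ([read_drug_response()]).
#' @param features 0/1 matrix, cell lines x features.
#' @param min_group minimum genotype-class size (default 3).
#' @param p_cutoff,fdr_cutoff,delta_cutoff hit cutoffs; defaults 0.001,
#'   0.25 and 1.4.
#' @param pool_screens compute BH across screens jointly.
#' @return data.frame of per-triple records (`pharmaco_hits`), volcano-ready.
#' @export
interaction_screen <- function(responses, features, min_group = 3,
                               p_cutoff = 0.001, fdr_cutoff = 0.25,
                               delta_cutoff = 1.4, pool_screens = FALSE) {
  if (is.null(features) || ncol(features) == 0) stop("empty feature set")
  rows <- list()
  key <- split(seq_len(nrow(responses)),
               paste(responses$drug, responses$screen, sep = "\r"))
  for (k in names(key)) {
    idx <- key[[k]]
    dk <- strsplit(k, "\r", fixed = TRUE)[[1]]
    vals <- responses$log10_ic50[idx]
    names(vals) <- responses$cell_line[idx]
    common <- intersect(names(vals), rownames(features))
    if (length(common) == 0) next
    v <- vals[common]
    for (f in colnames(features)) {
      rec <- pharmaco_one(v, features[common, f], min_group)
      rec <- cbind(data.frame(feature = f, drug = dk[1], screen_id = dk[2],
                              stringsAsFactors = FALSE), rec)
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  if (pool_screens) {
    t_ <- !out$untestable
    out$q[t_] <- stats::p.adjust(out$mw_p[t_], method = "BH")
  } else {
    for (s in unique(out$screen_id)) {
      t_ <- !out$untestable & out$screen_id == s
      out$q[t_] <- stats::p.adjust(out$mw_p[t_], method = "BH")
    }
  }
  out$direction <- ifelse(out$mean_diff < 0, "sensitivity", "resistance")
  gmin <- pmin(out$glass_delta_pos, out$glass_delta_neg)
  out$hit <- !out$untestable & out$mw_p < p_cutoff & out$q < fdr_cutoff &
    gmin > delta_cutoff
  out$hit[is.na(out$hit)] <- FALSE
  out[order(out$mw_p), ]
}

#' Anchor-only drug screen
#'
#' Restricts the interaction machinery to a single feature (the cytoband
#' loss anchor) across all drugs and screens. A drug present in two screens
#' yields two records tagged by screen. A record is a hit iff its BH q is
#' below both `q_cutoff` and `fdr_cutoff` and the smaller Glass' delta
#' exceeds `delta_cutoff`.
#'
#' @param responses drug-response data.frame.
#' @param anchor named 0/1 vector over cell lines.
#' @param q_cutoff adjusted-p cutoff (default 0.05).
#' @param fdr_cutoff,delta_cutoff,min_group as in [interaction_screen()].
#' @return data.frame of per-(drug, screen) records.
#' @export
anchor_screen <- function(responses, anchor, q_cutoff = 0.05,
                          fdr_cutoff = 0.25, delta_cutoff = 1.4,
                          min_group = 3) {
  if (length(unique(anchor)) < 2) stop("anchor feature is constant")
  features <- matrix(anchor, ncol = 1,
                     dimnames = list(names(anchor), "anchor"))
  out <- interaction_screen(responses, features, min_group = min_group,
                            p_cutoff = 1, fdr_cutoff = fdr_cutoff,
                            delta_cutoff = delta_cutoff)
  gmin <- pmin(out$glass_delta_pos, out$glass_delta_neg)
  out$hit <- !out$untestable & out$q < q_cutoff & out$q < fdr_cutoff &
    gmin > delta_cutoff
  out$hit[is.na(out$hit)] <- FALSE
  out
}

#' Two-group comparison of xenograft response values
#'
#' The anchor-loss vs wildtype machinery applied to per-model response
#' summaries (e.g. dose-response AUC): Mann-Whitney p, Glass' delta and
#' point-biserial r; no curve fitting.
#'
#' @param values named numeric response values (one per model).
#' @param anchor named 0/1 vector (1 = loss).
#' @param alternative passed to [mw_group_test()].
#' @return one-row data.frame of effect sizes and p value.
#' @export
pdx_response_test <- function(values, anchor,
                              alternative = "two_sided") {
  common <- intersect(names(values), names(anchor))
  v <- values[common]; a <- anchor[common]
  gd <- glass_delta(v[a == 1], v[a == 0])
  pb <- point_biserial(a, v)
  data.frame(n_pos = sum(a == 1), n_neg = sum(a == 0),
             mean_diff = gd$mean_diff, glass_delta_pos = gd$delta_pos,
             glass_delta_neg = gd$delta_neg,
             p_value = mw_group_test(v[a == 1], v[a == 0],
                                     alternative = alternative),
             r_pb = pb$r, magnitude = pb$magnitude,
             stringsAsFactors = FALSE)
}
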