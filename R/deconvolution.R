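# Bulk-expression deconvolution under the linear mixing model
# P_j = SM . beta_j + eps, solved per sample by non-negative least squares
# and renormalized to the probability simplex; ensemble averaging over a
# set of signature matrices; fraction contrasts between sample groups.

#' Prepare bulk expression for deconvolution
#'
#' Mirrors the two preprocessing modes used for the two source cohorts:
#' `"log2_scale"` (log2(x + 1), then per-gene scaling) or `"scale"`
#' (per-gene scaling only).
#'
#' @param expr numeric matrix, genes x samples.
#' @param mode `"scale"` or `"log2_scale"`.
#' @return transformed matrix.
#' @export
prep_expression <- function(expr, mode = c("scale", "log2_scale")) {
  mode <- match.arg(mode)
  if (mode == "log2_scale") expr <- log2(expr + 1)
  z <- zscore_by_gene(expr)
  z
}

#' Estimate cell-type fractions from bulk expression
#'
#' Per sample j solves `argmin_beta ||P_j - SM beta||^2 , beta >= 0` over
#' the genes shared between the bulk matrix and the signature matrix, then
#' renormalizes beta to sum 1. The residual norm `||P_j - SM beta_j||`
#' (the model's noise term) is stored per sample. Samples whose
#' unconstrained optimum is all-zero beta cannot be normalized; they
#' receive uniform fractions and are flagged.
#'
#' @param P numeric matrix, genes x samples (bulk profiles).
#' @param SM numeric matrix, genes x cell types; nonnegative mean
#'   expression of each gene in each cell type.
#' @return object of class `cell_fractions`: list with `fractions`
#'   (cell types x samples, columns on the simplex), `residual_norm`,
#'   `flagged`, `n_shared_genes`.
#' @export
estimate_fractions <- function(P, SM) {
  stopifnot(is.matrix(P), is.matrix(SM))
  if (ncol(SM) < 2) stop("need >= 2 cell types")
  shared <- intersect(rownames(P), rownames(SM))
  if (length(shared) == 0) stop("no shared genes between P and SM")
  bs_log("deconvolution over ", length(shared), " shared genes")
  A <- SM[shared, , drop = FALSE]
  if (qr(A)$rank < ncol(A))
    warning("rank-deficient signature matrix (condition number ",
            format(kappa(A), digits = 3), ")")
  B <- P[shared, , drop = FALSE]
  K <- ncol(A)
  frac <- matrix(NA_real_, K, ncol(B),
                 dimnames = list(colnames(A), colnames(B)))
  resid <- numeric(ncol(B))
  flagged <- character()
  for (j in seq_len(ncol(B))) {
    fit <- pracma::lsqnonneg(A, B[, j])
    beta <- fit$x
    resid[j] <- sqrt(sum((B[, j] - A %*% beta)^2))
    if (sum(beta) <= 0) {
      beta <- rep(1 / K, K)
      flagged <- c(flagged, colnames(B)[j])
    } else beta <- beta / sum(beta)
    frac[, j] <- beta
  }
  names(resid) <- colnames(B)
  structure(list(fractions = frac, residual_norm = resid, flagged = flagged,
                 n_shared_genes = length(shared)),
            class = "cell_fractions")
}

#' @export
print.cell_fractions <- function(x, ...) {
  cat("cell_fractions:", nrow(x$fractions), "cell types x",
      ncol(x$fractions), "samples")
  if (length(x$flagged)) cat(" (", length(x$flagged), "flagged )")
  cat("\n")
  invisible(x)
}

#' Average fraction estimates over a signature-matrix ensemble
#'
#' Element-wise mean of K per-signature-matrix estimates (harmonized by
#' cell-type name), renormalized per sample. Mismatched cell-type sets are
#' an error listing the differences.
#'
#' @param estimates list of `cell_fractions` objects.
#' @return `cell_fractions` with attribute `K` = ensemble size.
#' @export
ensemble_fractions <- function(estimates) {
  stopifnot(length(estimates) >= 1,
            all(vapply(estimates, inherits, TRUE, "cell_fractions")))
  types <- rownames(estimates[[1]]$fractions)
  samples <- colnames(estimates[[1]]$fractions)
  for (e in estimates[-1]) {
    dt <- c(setdiff(types, rownames(e$fractions)),
            setdiff(rownames(e$fractions), types))
    if (length(dt)) stop("mismatched cell types across estimates: ",
                         paste(dt, collapse = ", "))
    if (!setequal(samples, colnames(e$fractions)))
      stop("mismatched samples across estimates")
  }
  acc <- Reduce(`+`, lapply(estimates, function(e)
    e$fractions[types, samples, drop = FALSE]))
  avg <- acc / length(estimates)
  avg <- sweep(avg, 2, colSums(avg), `/`)
  res <- rowMeans(do.call(cbind, lapply(estimates, function(e)
    e$residual_norm[samples])))
  out <- structure(list(fractions = avg,
                        residual_norm = stats::setNames(res, samples),
                        flagged = unique(unlist(lapply(estimates,
                                                       `[[`, "flagged"))),
                        n_shared_genes = estimates[[1]]$n_shared_genes),
                   class = "cell_fractions")
  attr(out, "K") <- length(estimates)
  out
}

#' Compare cell-type fractions between two sample groups
#'
#' Per cell type: median fraction difference (loss - neutral) and a
#' two-sided independent rank-sum p value, BH-adjusted across cell types.
#' A type constant in both groups gets p = 1 and a flag.
#'
#' @param fractions a `cell_fractions` object.
#' @param groups named vector of `"loss"` / `"neutral"` labels per sample.
#' @return data.frame `cell_type`, `median_diff`, `p_value`, `q_value`,
#'   `constant`.
#' @export
compare_fractions <- function(fractions, groups) {
  fr <- fractions$fractions
  groups <- groups[names(groups) %in% colnames(fr)]
  loss_ids <- names(groups)[groups == "loss"]
  neut_ids <- names(groups)[groups == "neutral"]
  if (length(loss_ids) < 2 || length(neut_ids) < 2)
    stop("both groups need >= 2 samples")
  rows <- lapply(rownames(fr), function(ct) {
    xl <- fr[ct, loss_ids]; xn <- fr[ct, neut_ids]
    const <- stats::sd(c(xl, xn)) == 0
    p <- if (const) 1 else rank_sum_p(xl, xn)
    data.frame(cell_type = ct,
               median_diff = stats::median(xl) - stats::median(xn),
               p_value = p, constant = const, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), c("cell_type", "median_diff", "p_value",
                            "q_value", "constant")]
}

#' Cross-cohort consistency of fraction contrasts
#'
#' A cell type is consistent when its median difference has the same sign
#' and its BH q value is below `q_cutoff` in both cohorts. Types absent
#' from either cohort are excluded and reported.
#'
#' @param contrast_a,contrast_b data.frames from [compare_fractions()].
#' @param q_cutoff q-value threshold (default 0.05).
#' @return data.frame with per-type consistency flags; attribute
#'   `excluded` lists cell types present in only one cohort.
#' @export
consistent_fraction_shifts <- function(contrast_a, contrast_b,
                                       q_cutoff = 0.05) {
  shared <- intersect(contrast_a$cell_type, contrast_b$cell_type)
  excl <- c(setdiff(contrast_a$cell_type, shared),
            setdiff(contrast_b$cell_type, shared))
  m <- merge(contrast_a, contrast_b, by = "cell_type",
             suffixes = c("_a", "_b"))
  m$consistent <- sign(m$median_diff_a) == sign(m$median_diff_b) &
    m$q_value_a < q_cutoff & m$q_value_b < q_cutoff
  attr(m, "excluded") <- excl
  m
}
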