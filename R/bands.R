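# Cytoband-level summarization of gene-level GISTIC-thresholded calls.

CN_STATUS_MAP <- c(`-2` = "deep_loss", `-1` = "loss", `0` = "neutral",
                   `1` = "gain", `2` = "amplification")

#' Assign genes to cytobands by interval midpoint
#'
#' A gene belongs to the band containing the midpoint of its interval
#' (0-based half-open on both sides). Genes whose midpoint falls outside
#' every band of their chromosome are reported as unassigned, not an error.
#'
#' @param annotation a [genome_annotation()].
#' @return list with `assignment` (data.frame `gene_id`, `band_name`) and
#'   `unassigned` (character vector of gene ids).
#' @export
assign_genes_to_bands <- function(annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  bands <- annotation$bands
  band_of <- rep(NA_character_, nrow(genes))
  mid <- (genes$start + genes$end) %/% 2L
  for (ch in unique(genes$chrom)) {
    gi <- which(genes$chrom == ch)
    b <- bands[bands$chrom == ch, ]
    if (nrow(b) == 0) next
    # bands are sorted and non-overlapping (reader invariant)
    k <- findInterval(mid[gi], b$start)
    inside <- k >= 1 & mid[gi] < b$end[pmax(k, 1L)]
    band_of[gi[inside]] <- b$band_name[k[inside]]
  }
  list(assignment = data.frame(gene_id = genes$gene_id,
                               band_name = band_of,
                               stringsAsFactors = FALSE)[!is.na(band_of), ],
       unassigned = genes$gene_id[is.na(band_of)])
}

#' Call the copy-number status of one band in one sample
#'
#' If all non-missing gene values agree, the shared value maps to
#' `deep_loss` (-2), `loss` (-1), `neutral` (0), `gain` (+1) or
#' `amplification` (+2). Two or more distinct non-missing values imply an
#' intra-band breakpoint and yield `ambiguous`; no non-missing values yield
#' `missing`.
#'
#' @param gene_values integer vector of per-gene CN codes, possibly with
#'   `NA`.
#' @return one of `deep_loss`, `loss`, `neutral`, `gain`, `amplification`,
#'   `ambiguous`, `missing`.
#' @export
call_band_status <- function(gene_values) {
  v <- gene_values[!is.na(gene_values)]
  if (length(v) && !all(v %in% -2:2))
    stop("CN value outside {-2..2}: ", v[!v %in% -2:2][1])
  u <- unique(v)
  if (length(u) == 0) return("missing")
  if (length(u) > 1) return("ambiguous")
  CN_STATUS_MAP[[as.character(u)]]
}

#' Per-sample band status table
#'
#' Applies [call_band_status()] to every (band, sample) pair. Bands with no
#' annotated gene in the CN matrix are absent from the table.
#'
#' @param cn gene-level CN matrix.
#' @param annotation a [genome_annotation()].
#' @return character matrix (bands x samples) of statuses with attribute
#'   `band_info` (chromosome and start per band, in genomic order).
#' @export
band_status_table <- function(cn, annotation) {
  validate_cn_matrix(cn)
  asg <- assign_genes_to_bands(annotation)$assignment
  asg <- asg[asg$gene_id %in% rownames(cn), ]
  if (nrow(asg) == 0) stop("no CN gene maps to any band")
  bands <- annotation$bands
  bands <- bands[bands$band_name %in% asg$band_name, ]
  ord <- order(bands$chrom, bands$start)
  bands <- bands[ord, ]
  out <- matrix(NA_character_, nrow(bands), ncol(cn),
                dimnames = list(bands$band_name, colnames(cn)))
  by_band <- split(asg$gene_id, asg$band_name)
  for (b in bands$band_name) {
    sub <- cn[by_band[[b]], , drop = FALSE]
    out[b, ] <- apply(sub, 2, call_band_status)
  }
  attr(out, "band_info") <- data.frame(band_name = bands$band_name,
                                       chrom = bands$chrom,
                                       start = bands$start,
                                       stringsAsFactors = FALSE)
  out
}

#' Rank bands by loss frequency
#'
#' Frequency = samples with status in `loss_def` over samples with a
#' callable (non-missing) status; `ambiguous` counts in the denominator but
#' in no numerator. Ties in frequency are broken by genomic order
#' (chromosome, then start).
#'
#' @param status_table matrix from [band_status_table()].
#' @param loss_def statuses counted as loss.
#' @return data.frame `band_name`, `n_callable`, `n_loss`, `frequency`,
#'   `rank`, sorted by rank.
#' @export
band_loss_frequencies <- function(status_table,
                                  loss_def = c("loss", "deep_loss")) {
  if (length(status_table) == 0 || nrow(status_table) == 0)
    stop("empty band status table")
  info <- attr(status_table, "band_info")
  callable <- rowSums(status_table != "missing")
  nl <- rowSums(matrix(status_table %in% loss_def, nrow(status_table)))
  freq <- ifelse(callable > 0, nl / callable, NA_real_)
  ord <- order(-freq, info$chrom, info$start)
  out <- data.frame(band_name = rownames(status_table),
                    chrom = info$chrom, start = info$start,
                    n_callable = callable, n_loss = nl, frequency = freq,
                    stringsAsFactors = FALSE)[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Compare per-gene alteration frequency inside vs outside a band
#'
#' The replicate unit is the gene: for each gene the fraction of samples
#' altered in the requested direction (loss: value < 0; gain: value > 0) is
#' computed over non-missing calls, and the in-band set is compared with all
#' other genes by a two-sample Student t test (equal variances).
#'
#' @param cn gene-level CN matrix.
#' @param annotation a [genome_annotation()].
#' @param anchor_band band name, e.g. `"13q14.2"`.
#' @param mode `"loss"` or `"gain"`.
#' @return list with `t`, `p`, `mean_in`, `mean_out`, `n_in`, `n_out`.
#' @export
compare_band_vs_genome <- function(cn, annotation, anchor_band,
                                   mode = c("loss", "gain")) {
  mode <- match.arg(mode)
  asg <- assign_genes_to_bands(annotation)$assignment
  in_genes <- intersect(asg$gene_id[asg$band_name == anchor_band],
                        rownames(cn))
  out_genes <- setdiff(rownames(cn), in_genes)
  if (length(in_genes) < 2 || length(out_genes) < 2)
    stop("need >= 2 genes inside and outside the anchor band")
  altered <- if (mode == "loss") cn < 0 else cn > 0
  freq <- rowMeans(altered, na.rm = TRUE)
  fi <- freq[in_genes]; fo <- freq[out_genes]
  if (stats::sd(fi) == 0 && stats::sd(fo) == 0) {
    if (isTRUE(all.equal(mean(fi), mean(fo))))
      return(list(t = 0, p = 1, mean_in = mean(fi), mean_out = mean(fo),
                  n_in = length(fi), n_out = length(fo)))
    stop("degenerate variance: both gene groups constant")
  }
  tt <- stats::t.test(fi, fo, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_in = mean(fi), mean_out = mean(fo),
       n_in = length(fi), n_out = length(fo))
}

#' Band status by clinical subtype, with chi-square test
#'
#' Cross-tabulates the anchor band's status categories against a subtype
#' grouping and applies Pearson's chi-square test without continuity
#' correction. Cells with expected counts below 5 raise a flag but never
#' suppress the statistic.
#'
#' @param statuses named character vector of band statuses per sample.
#' @param clinical clinical data.frame with `sample_id` and grouping column.
#' @param grouping `"pam50"` or `"er_her2"` (the latter combines `er` and
#'   `her2` into four groups).
#' @param drop_statuses statuses removed before tabulation (default:
#'   `missing`).
#' @return list with `table`, `chi2`, `df`, `p`, `low_expected`.
#' @export
subtype_status_table <- function(statuses, clinical,
                                 grouping = c("pam50", "er_her2"),
                                 drop_statuses = "missing") {
  grouping <- match.arg(grouping)
  grp <- if (grouping == "pam50") clinical$pam50 else
    paste0("ER", clinical$er, "/HER2", clinical$her2)
  names(grp) <- clinical$sample_id
  common <- intersect(names(statuses), names(grp))
  st <- statuses[common]; gg <- grp[common]
  keep <- !st %in% drop_statuses & !is.na(gg)
  st <- st[keep]; gg <- gg[keep]
  if (length(unique(gg)) < 2) stop("need >= 2 subtype levels")
  tab <- table(status = st, subtype = gg)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab, chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, low_expected = any(ct$expected < 5))
}
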