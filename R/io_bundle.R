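# Cohort bundle assembly, sample exclusion and ID matching.

#' Assemble a cohort bundle
#'
#' Binds the per-cohort tables (copy number, mutations, optional expression,
#' clinical, genome annotation) into one object and starts a provenance log
#' to which every downstream filter appends.
#'
#' @param cn integer CN matrix (genes x samples), values in \{-2..2\} or `NA`.
#' @param mutations mutation data.frame as from [read_mutation_table()].
#' @param clinical clinical data.frame as from [read_clinical_table()].
#' @param annotation a [genome_annotation()].
#' @param expression optional expression matrix (genes x samples).
#' @return object of class `cohort_bundle`.
#' @export
cohort_bundle <- function(cn, mutations, clinical, annotation,
                          expression = NULL) {
  validate_cn_matrix(cn)
  if (anyDuplicated(colnames(cn))) stop("duplicate sample ids in CN matrix")
  if (anyDuplicated(clinical$sample_id))
    stop("duplicate sample ids in clinical table")
  structure(list(cn = cn, mutations = mutations, clinical = clinical,
                 annotation = annotation, expression = expression,
                 log = sprintf("bundle assembled: %d samples, %d genes",
                               ncol(cn), nrow(cn)),
                 exclusion_report = NULL),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", ncol(x$cn), "samples,", nrow(x$cn), "CN genes,",
      nrow(x$mutations), "mutation records\n")
  for (l in x$log) cat(" -", l, "\n")
  invisible(x)
}

#' Exclude carriers of pathogenic mutations in given genes
#'
#' Removes every sample carrying at least one mutation flagged pathogenic in
#' any of the listed genes from all tables of the bundle (mirroring the
#' removal of pathogenic \emph{RB1}-mutant samples before any 13q14.2
#' analysis). Samples with only non-pathogenic mutations in those genes are
#' retained. Values of retained samples are untouched.
#'
#' @param bundle a [cohort_bundle()].
#' @param genes character vector of gene ids; must resolve in the
#'   annotation. An empty vector is the identity transform.
#' @return the filtered bundle; `$exclusion_report` holds a data.frame of
#'   `(sample_id, gene_id)` pairs that triggered removal.
#' @export
exclude_pathogenic_carriers <- function(bundle, genes) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (length(genes) == 0) {
    bundle$exclusion_report <- data.frame(sample_id = character(),
                                          gene_id = character())
    return(bundle)
  }
  known <- bundle$annotation$genes$gene_id
  unknown <- setdiff(genes, known)
  if (length(unknown)) stop("unknown gene id(s): ",
                            paste(unknown, collapse = ", "))
  mut <- bundle$mutations
  hit <- mut$pathogenic & mut$gene_id %in% genes
  report <- unique(mut[hit, c("sample_id", "gene_id")])
  rownames(report) <- NULL
  drop <- unique(report$sample_id)
  keep_cn <- setdiff(colnames(bundle$cn), drop)
  bundle$cn <- bundle$cn[, keep_cn, drop = FALSE]
  if (!is.null(bundle$expression)) {
    keep_e <- setdiff(colnames(bundle$expression), drop)
    tag <- attr(bundle$expression, "scale_tag")
    bundle$expression <- bundle$expression[, keep_e, drop = FALSE]
    attr(bundle$expression, "scale_tag") <- tag
  }
  bundle$clinical <- bundle$clinical[!bundle$clinical$sample_id %in% drop, ,
                                     drop = FALSE]
  bundle$mutations <- mut[!mut$sample_id %in% drop, , drop = FALSE]
  bundle$exclusion_report <- report
  bundle$log <- c(bundle$log,
                  sprintf("excluded %d pathogenic carrier(s) of [%s]",
                          length(drop), paste(genes, collapse = ",")))
  bundle
}

#' Match copy-number samples to clinical rows by patient identifier
#'
#' Applies a documented identifier normalizer to both sides and builds a
#' one-to-one sample-to-patient mapping. The default normalizer truncates
#' TCGA-style barcodes to the 12-character patient prefix and leaves shorter
#' identifiers untouched. Unmatched entries on either side are reported, not
#' silently dropped; two CN samples resolving to the same patient is an
#' error.
#'
#' @param cn_samples character vector of CN sample ids.
#' @param clinical clinical data.frame with a `sample_id` column.
#' @param id_normalizer function mapping an id vector to patient-level ids.
#' @return data.frame `(sample_id, patient_id)` of matches, with attributes
#'   `unmatched_samples` and `unmatched_clinical`.
#' @export
match_by_patient_id <- function(cn_samples, clinical,
                                id_normalizer = tcga_patient_id) {
  pat <- id_normalizer(cn_samples)
  if (anyDuplicated(pat)) {
    coll <- split(cn_samples, pat)
    coll <- coll[vapply(coll, length, 1L) > 1]
    stop("id normalizer maps multiple CN samples to one patient: ",
         paste(vapply(coll, paste, "", collapse = "/"), collapse = "; "))
  }
  cpat <- id_normalizer(clinical$sample_id)
  if (anyDuplicated(cpat)) stop("id normalizer collides clinical rows")
  idx <- match(pat, cpat)
  out <- data.frame(sample_id = cn_samples[!is.na(idx)],
                    patient_id = pat[!is.na(idx)],
                    stringsAsFactors = FALSE)
  attr(out, "unmatched_samples") <- cn_samples[is.na(idx)]
  attr(out, "unmatched_clinical") <-
    clinical$sample_id[!cpat %in% pat]
  out
}

#' TCGA barcode to patient-level id
#'
#' Truncates identifiers longer than 12 characters to the 12-character
#' patient prefix (`TCGA-XX-YYYY`); shorter ids pass through.
#'
#' @param x character vector of sample ids.
#' @return character vector of patient ids.
#' @export
tcga_patient_id <- function(x) {
  ifelse(nchar(x) > 12 & startsWith(x, "TCGA-"), substr(x, 1, 12), x)
}
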