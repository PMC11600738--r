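#' @keywords internal
"_PACKAGE"

# ---- logging --------------------------------------------------------------

bs_log <- function(..., level = "info") {
  lv <- getOption("bandscape.log_level", "info")
  rank <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (rank[[level]] >= rank[[lv]]) message("[bandscape] ", ...)
  invisible(NULL)
}

# ---- gene-level CN matrix -------------------------------------------------

#' Read a gene-level GISTIC-thresholded copy-number matrix
#'
#' Reads a cBioPortal `data_CNA`-style TSV: first column gene symbols, one
#' column per sample, integer calls in \{-2, -1, 0, 1, 2\} (-2 deep loss,
#' -1 one-copy loss, 0 diploid, +1 gain, +2 amplification). Blank cells are
#' recorded as missing (`NA`). Out-of-contract cells are rejected, never
#' coerced.
#'
#' @param path path to the TSV file.
#' @param dialect input dialect; only `"cbioportal_tsv"` is supported.
#' @return integer matrix, genes as rows, samples as columns.
#' @export
read_gene_cn_matrix <- function(path, dialect = "cbioportal_tsv") {
  dialect <- match.arg(dialect, "cbioportal_tsv")
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  samples <- colnames(raw)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample header(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- raw[[1]]
  if (anyDuplicated(genes))
    stop("duplicate gene row(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals[vals == ""] <- NA_character_
  ok <- is.na(vals) | vals %in% c("-2", "-1", "0", "1", "2")
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer or out-of-range CN value %s at (gene %s, sample %s)",
                 vals[bad[1], bad[2]], genes[bad[1]], samples[bad[2]]))
  }
  m <- matrix(as.integer(vals), nrow = length(genes),
              dimnames = list(genes, samples))
  bs_log("read CN matrix: ", nrow(m), " genes x ", ncol(m), " samples, ",
         sum(is.na(m)), " missing cells")
  m
}

#' Write a gene-level copy-number matrix
#'
#' Inverse of [read_gene_cn_matrix()]: round-trips valid matrices.
#'
#' @param cn integer matrix with gene rownames and sample colnames.
#' @param path output path.
#' @export
write_gene_cn_matrix <- function(cn, path) {
  validate_cn_matrix(cn)
  df <- data.frame(gene_id = rownames(cn), cn, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

validate_cn_matrix <- function(cn) {
  stopifnot(is.matrix(cn), !is.null(rownames(cn)), !is.null(colnames(cn)))
  if (anyDuplicated(rownames(cn))) stop("duplicate gene ids in CN matrix")
  bad <- !(is.na(cn) | cn %in% -2:2)
  if (any(bad)) stop("CN values outside {-2..2}: first offender ",
                     cn[which(bad)[1]])
  invisible(cn)
}

# ---- genome annotation ----------------------------------------------------

#' Read a UCSC cytoBand.txt cytoband table
#'
#' Rows are `chrom start end name stain` with 0-based half-open coordinates,
#' which are kept as-is internally. Band names are composed as
#' `<chrom without "chr"><name>`, e.g. `13q14.2`. Overlapping bands on one
#' chromosome are an error.
#'
#' @param path path to a whitespace- or tab-delimited cytoband file.
#' @return data.frame with columns `chrom`, `start`, `end`, `band_name`,
#'   `stain`, sorted by chromosome then start.
#' @export
read_cytoband_annotation <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warning("empty cytoband file: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), band_name = character(),
                      stain = character()))
  }
  raw <- utils::read.table(path, header = FALSE, col.names =
                             c("chrom", "start", "end", "name", "stain"),
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  chrom <- sub("^chr", "", raw$chrom)
  bands <- data.frame(chrom = chrom, start = raw$start, end = raw$end,
                      band_name = paste0(chrom, raw$name), stain = raw$stain,
                      stringsAsFactors = FALSE)
  bands <- bands[order(bands$chrom, bands$start), ]
  rownames(bands) <- NULL
  for (ch in unique(bands$chrom)) {
    b <- bands[bands$chrom == ch, ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) {
      i <- which(b$start[-1] < b$end[-nrow(b)])[1]
      stop(sprintf("overlapping bands on chromosome %s: %s and %s",
                   ch, b$band_name[i], b$band_name[i + 1]))
    }
    if (any(b$start >= b$end)) stop("band with start >= end on chromosome ", ch)
  }
  bands
}

#' Read gene positions
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`. Coordinates are
#' declared 1-based inclusive in the file and converted to the package's
#' internal 0-based half-open convention here, at the boundary.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @export
read_gene_positions <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  g <- data.frame(gene_id = as.character(raw$gene_id),
                  chrom = sub("^chr", "", as.character(raw$chrom)),
                  start = as.integer(raw$start) - 1L,
                  end = as.integer(raw$end), stringsAsFactors = FALSE)
  if (any(g$start >= g$end)) stop("gene interval with start >= end")
  if (anyDuplicated(g$gene_id)) stop("duplicate gene ids in gene positions")
  g
}

#' Assemble a genome annotation
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param bands data.frame as returned by [read_cytoband_annotation()].
#' @return list of class `genome_annotation` with elements `genes`, `bands`.
#' @export
genome_annotation <- function(genes, bands) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% colnames(genes)),
            all(c("chrom", "start", "end", "band_name") %in% colnames(bands)))
  if (any(genes$start >= genes$end)) stop("gene interval with start >= end")
  structure(list(genes = genes, bands = bands), class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$genes), "genes,", nrow(x$bands),
      "bands on", length(unique(x$bands$chrom)), "chromosomes\n")
  invisible(x)
}

# ---- flat tables ----------------------------------------------------------

#' Read a mutation table
#'
#' TSV with columns `sample_id`, `gene_id`, `class`, `pathogenic`
#' (true/false). A missing or blank pathogenicity entry defaults to `FALSE`
#' (pathogenicity is an input flag, e.g. a ClinVar annotation done upstream).
#'
#' @param path path to the TSV file.
#' @return data.frame with `sample_id`, `gene_id`, `class`, `pathogenic`.
#' @export
read_mutation_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "gene_id", "class")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  path_flag <- if ("pathogenic" %in% colnames(raw)) {
    p <- tolower(raw$pathogenic)
    p[is.na(p) | p == ""] <- "false"
    if (!all(p %in% c("true", "false")))
      stop("pathogenic column must be true/false")
    p == "true"
  } else rep(FALSE, nrow(raw))
  out <- data.frame(sample_id = raw$sample_id, gene_id = raw$gene_id,
                    class = raw$class, pathogenic = path_flag,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("sample_id", "gene_id", "class")]))
    stop("duplicate (sample_id, gene_id, class) mutation records")
  bs_log("read mutation table: ", nrow(out), " records")
  out
}

#' Read an expression matrix (TSV, genes x samples)
#'
#' @param path path; first column `gene_id` (or protein id), remaining
#'   columns numeric sample values.
#' @param scale_tag how values are scaled: `"raw"`, `"log2"` or `"zscore"`.
#' @return numeric matrix with a `scale_tag` attribute.
#' @export
read_expression_matrix <- function(path, scale_tag = c("raw", "log2", "zscore")) {
  scale_tag <- match.arg(scale_tag)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, quote = "")
  if (anyDuplicated(raw[[1]])) stop("duplicate gene ids in expression matrix")
  m <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values")
  rownames(m) <- as.character(raw[[1]])
  attr(m, "scale_tag") <- scale_tag
  bs_log("read expression matrix: ", nrow(m), " x ", ncol(m))
  m
}

#' Read a clinical table
#'
#' TSV with columns `sample_id`, `pam50`, `er`, `her2`, `os_months`,
#' `os_event`. Missing covariates are allowed (blank), but negative survival
#' times or events outside \{0,1\} are rejected.
#'
#' @param path path to the TSV file.
#' @return data.frame of per-sample clinical covariates.
#' @export
read_clinical_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("sample_id", "pam50", "er", "her2", "os_months", "os_event")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(raw$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(raw$os_months < 0, na.rm = TRUE))
    stop("negative os_months in clinical table")
  if (!all(raw$os_event %in% c(0, 1, NA)))
    stop("os_event must be 0/1")
  bs_log("read clinical table: ", nrow(raw), " rows")
  raw
}

#' Read gene sets from a GMT file
#'
#' @param path GMT path: per line, set name, description, then member genes,
#'   tab-separated.
#' @return named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names in GMT")
  sets
}

#' Read a drug-response table
#'
#' CSV with columns `cell_line`, `drug`, `screen`, `log10_ic50` (GDSC-like,
#' log10 of the half-maximal inhibitory concentration). Rows with a
#' malformed IC50 are skipped and counted, not fatal.
#'
#' @param path CSV path.
#' @return data.frame with the four columns; attribute `n_skipped` records
#'   dropped rows.
#' @export
read_drug_response <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("cell_line", "drug", "screen", "log10_ic50")
  miss <- setdiff(need, colnames(raw))
  if (length(miss)) stop("missing mandatory column(s): ",
                         paste(miss, collapse = ", "))
  ic <- suppressWarnings(as.numeric(raw$log10_ic50))
  bad <- !is.finite(ic)
  if (any(bad)) bs_log("skipped ", sum(bad), " malformed drug-response rows",
                       level = "warn")
  out <- data.frame(cell_line = raw$cell_line[!bad], drug = raw$drug[!bad],
                    screen = raw$screen[!bad], log10_ic50 = ic[!bad],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out[c("cell_line", "drug", "screen")]))
    stop("duplicate (cell_line, drug, screen) records")
  attr(out, "n_skipped") <- sum(bad)
  out
}
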