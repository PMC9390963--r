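#' Read a gene x sample expression matrix from TSV
#'
#' First column = gene id (unique), header = sample ids (unique); all cells
#' numeric and non-negative.
#'
#' @param path TSV path.
#' @param layer layer tag to attach (`"counts"`, `"TPM"`, ...).
#' @return gene x sample numeric matrix.
#' @export
read_matrix <- function(path, layer = "counts") {
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(df) < 2) abort("matrix TSV needs a gene column and >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    abort(paste("duplicate gene id(s):",
                paste(unique(genes[duplicated(genes)]), collapse = ", ")))
  }
  samples <- names(df)[-1]
  if (anyDuplicated(samples)) abort("duplicate sample ids in header")
  vals <- matrix(NA_real_, length(genes), length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) & !is.na(df[[j + 1]]))
    if (length(bad)) {
      abort(sprintf("non-numeric cell at row %d, column '%s'",
                    bad[1], samples[j]))
    }
    if (anyNA(v)) abort(sprintf("missing value in column '%s'", samples[j]))
    vals[, j] <- v
  }
  if (any(vals < 0)) {
    idx <- which(vals < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at gene '%s', sample '%s'",
                  genes[idx[1]], samples[idx[2]]))
  }
  set_expr_layer(vals, layer)
}

#' Write a gene x sample matrix to TSV
#'
#' @param matrix gene x sample matrix.
#' @param path output path.
#' @param id_column name of the gene-id column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path, id_column = "gene") {
  df <- as_tibble(matrix, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read / write BED6 interval files
#'
#' BED6 columns: chrom, start, end, name, score, strand; 0-based half-open.
#' `read_bed6` returns a tibble with those columns.
#'
#' @param path file path.
#' @return tibble (read) or `path` invisibly (write).
#' @export
read_bed6 <- function(path) {
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start", "end", "name",
                                      "score", "strand"),
                        col_types = "ciicdc", progress = FALSE)
  if (any(df$start >= df$end)) abort("BED intervals must satisfy start < end")
  df
}

#' @param intervals tibble with columns chrom, start, end, name and
#'   optionally score, strand.
#' @rdname read_bed6
#' @export
write_bed6 <- function(intervals, path) {
  df <- tibble(
    chrom = intervals$chrom, start = intervals$start, end = intervals$end,
    name = intervals$name,
    score = intervals$score %||% 0,
    strand = intervals$strand %||% "."
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write a TSS table as BED6
#'
#' TSS records become 1-bp intervals `[tss, tss + 1)` named by gene.
#'
#' @param tss tibble: gene, chrom, tss, strand.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  write_bed6(tibble(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1,
                    name = tss$gene, score = 0, strand = tss$strand), path)
}

#' Read a TSS BED6 file back into a TSS table
#'
#' @param path BED6 path written by [write_tss_bed()].
#' @return tibble: gene, chrom, tss, strand.
#' @export
read_tss_bed <- function(path) {
  b <- read_bed6(path)
  if (anyDuplicated(b$name)) {
    warn("duplicate TSS records; keeping the first per gene")
    b <- b[!duplicated(b$name), , drop = FALSE]
  }
  tibble(gene = b$name, chrom = b$chrom, tss = b$start, strand = b$strand)
}

#' Write a TFBS table as BED6
#'
#' @param tfbs tibble: tf, chrom, start, end.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tfbs_bed <- function(tfbs, path) {
  write_bed6(tibble(chrom = tfbs$chrom, start = tfbs$start, end = tfbs$end,
                    name = tfbs$tf, score = 0, strand = "."), path)
}

#' Read a TFBS BED6 file back into a TFBS table
#'
#' @param path BED6 path written by [write_tfbs_bed()].
#' @return tibble: tf, chrom, start, end.
#' @export
read_tfbs_bed <- function(path) {
  b <- read_bed6(path)
  tibble(tf = b$name, chrom = b$chrom, start = b$start, end = b$end)
}
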