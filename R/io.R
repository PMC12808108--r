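#' Read and write the package's tab-separated interchange tables
#'
#' Thin wrappers around [utils::read.delim()] / [utils::write.table()]
#' fixing the conventions used by every table this package exchanges:
#' tab-separated, header line, no quoting, no row names.
#'
#' @param path File path.
#' @param x data.frame to write.
#' @return `read_tsv()` returns a data.frame; `write_tsv()` returns `path`
#'   invisibly.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene set stored as one symbol per line
#'
#' @param path File path; blank lines and duplicates are dropped.
#' @return Character vector of gene symbols.
#' @export
read_gene_set <- function(path) {
  x <- readLines(path)
  unique(x[nzchar(trimws(x))])
}

#' Write allele-resolved UMI matrices as an MTX pair with shared indices
#'
#' Writes `ref.mtx`, `alt.mtx`, `barcodes.tsv` (one barcode per line) and
#' `variants.tsv` (variant_id, gene, par_flag) into a directory, the
#' plain-text layout used for allele-resolved single-cell counts.
#'
#' @param ref_umis,alt_umis Sparse matrices (cells x variants) with shared
#'   dimnames.
#' @param variant_info data.frame as accepted by [score_cells()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_allele_mtx <- function(ref_umis, alt_umis, variant_info, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(.as_csparse(ref_umis), file.path(dir, "ref.mtx"))
  Matrix::writeMM(.as_csparse(alt_umis), file.path(dir, "alt.mtx"))
  writeLines(rownames(ref_umis), file.path(dir, "barcodes.tsv"))
  write_tsv(variant_info, file.path(dir, "variants.tsv"))
  invisible(dir)
}

#' Read an allele-resolved MTX pair written by [write_allele_mtx()]
#'
#' @param dir Directory containing `ref.mtx`, `alt.mtx`, `barcodes.tsv`,
#'   `variants.tsv`.
#' @return list with `ref_umis`, `alt_umis` (dgCMatrix, cells x variants)
#'   and `variant_info`.
#' @export
read_allele_mtx <- function(dir) {
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  vi <- read_tsv(file.path(dir, "variants.tsv"))
  dn <- list(barcodes, vi$variant_id)
  load1 <- function(f) {
    m <- methods::as(Matrix::readMM(file.path(dir, f)), "CsparseMatrix")
    dimnames(m) <- dn
    m
  }
  list(ref_umis = load1("ref.mtx"), alt_umis = load1("alt.mtx"),
       variant_info = vi)
}
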