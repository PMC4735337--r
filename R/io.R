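# Plain-text I/O: tab-delimited gene-by-sample matrices, annotation tables,
# gene panels, and optional MatrixMarket sparse output.

#' Write / read a gene-by-sample count matrix as TSV
#'
#' First column `gene_id`, header row of sample identifiers.
#'
#' @param counts Genes-by-samples matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  check_count_matrix(counts)
  df <- tibble::as_tibble(counts, rownames = "gene_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read a sample annotation table as TSV
#'
#' Columns `sample_id`, `subtype`, `ER`, `PR`, `Her2` (hidden truth columns,
#' when present, are preserved).
#'
#' @param annotation Annotation tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  readr::write_tsv(annotation, path)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  if ("subtype" %in% names(ann)) {
    lv <- intersect(subtype_levels(), unique(ann$subtype))
    ann$subtype <- factor(ann$subtype, levels = if (length(lv)) lv else NULL)
  }
  for (col in intersect(c("ER", "PR", "Her2"), names(ann))) {
    ann[[col]] <- factor(ann[[col]], levels = c("neg", "pos"))
  }
  tibble::as_tibble(ann)
}

#' Read a gene panel (one identifier per line)
#'
#' @param path Text file with one gene ID per line; blank lines and `#`
#'   comments are ignored.
#' @return Character vector of gene identifiers.
#' @export
read_gene_panel <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a count matrix in MatrixMarket coordinate format
#'
#' Writes `<stem>.mtx` plus `<stem>.genes.txt` and `<stem>.samples.txt` index
#' files (one identifier per line), the conventional sparse triplet layout.
#'
#' @param counts Genes-by-samples matrix.
#' @param stem Output path stem (without extension).
#' @return The `.mtx` path, invisibly.
#' @export
write_count_mtx <- function(counts, stem) {
  check_count_matrix(counts)
  nz <- which(counts != 0, arr.ind = TRUE)
  path <- paste0(stem, ".mtx")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("%%MatrixMarket matrix coordinate integer general", con)
  writeLines(sprintf("%d %d %d", nrow(counts), ncol(counts), nrow(nz)), con)
  if (nrow(nz) > 0L) {
    writeLines(
      sprintf("%d %d %d", nz[, 1L], nz[, 2L], counts[nz]), con
    )
  }
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  invisible(path)
}
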