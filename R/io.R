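#' Similarity/distance matrix TSV round-trip
#'
#' Matrices are written with a header row and column of IDs plus `#key value`
#' metadata comment lines (measure, method, w_e, log base, ...), so a run can
#' be reproduced from its outputs alone.
#'
#' @param m labeled numeric matrix
#' @param file output path
#' @param metadata named list/vector of scalar metadata to record
#' @return `file`, invisibly
#' @export
write_matrix_tsv <- function(m, file, metadata = list()) {
  auto <- list(
    measure = attr(m, "measure"),
    method = attr(m, "method"),
    w_e = attr(m, "w_e")
  )
  auto <- auto[!vapply(auto, is.null, logical(1))]
  metadata <- utils::modifyList(auto, as.list(metadata))
  meta_lines <- sprintf("#%s\t%s", names(metadata),
                        vapply(metadata, format, character(1)))
  header <- paste(c("id", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(meta_lines, header, body), file)
  invisible(file)
}

#' @rdname write_matrix_tsv
#' @return for `read_matrix_tsv`: the matrix, with metadata restored in the
#'   `metadata` attribute
#' @export
read_matrix_tsv <- function(file) {
  lines <- readLines(file, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- parts[[1L]][-1L]
  m <- do.call(rbind, lapply(parts[-1L], function(p) as.numeric(p[-1L])))
  rownames(m) <- vapply(parts[-1L], `[[`, character(1), 1L)
  colnames(m) <- ids
  meta <- strsplit(sub("^#", "", meta_lines), "\t", fixed = TRUE)
  md <- stats::setNames(
    lapply(meta, `[[`, 2L),
    vapply(meta, `[[`, character(1), 1L)
  )
  attr(m, "metadata") <- md
  m
}

#' Write enrichment records or module statistics as TSV
#'
#' @param df a data.frame (e.g. from [enrich()] or [module_significance()])
#' @param file output path
#' @return `file`, invisibly
#' @export
write_records_tsv <- function(df, file) {
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a plain-text ID list
#'
#' One ID per line; blank lines and `#` comments are ignored.
#'
#' @param file path
#' @return character vector
#' @export
read_id_list <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines[nzchar(lines) & !grepl("^#", lines)]
}
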