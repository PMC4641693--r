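#' Read a FASTA file of pre-miRNA sequences
#'
#' Wrapped and single-line dialects are both accepted; sequences are
#' normalized to uppercase RNA (T to U) and validated against
#' `{A,C,G,T,U,N}`; ids (the first whitespace-delimited token of each
#' header) must be unique.
#'
#' @param path file path.
#' @return named character vector of RNA sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) ml_stop("no FASTA records found", "mirlocate_data_error")
  ids <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr]))
  if (anyDuplicated(ids))
    ml_stop(paste("duplicate FASTA id:", ids[duplicated(ids)][1]),
            "mirlocate_duplicate_id")
  rec <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1),
                 collapse = "")
  seqs <- vapply(seqs, normalize_rna, character(1))
  stats::setNames(unname(seqs), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path file path.
#' @param width line-wrap width.
#' @param header optional provenance comment lines (written with `#`).
#' @export
write_fasta <- function(seqs, path, width = 60, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read an annotation table
#'
#' Tab-separated with a header row; either the sequence dialect
#' (`premirna_id`, `mirna_seq`) or the coordinate dialect (`premirna_id`,
#' `start`, `end`, 1-based inclusive).
#'
#' @param path file path.
#' @return data.frame in the declared dialect.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"premirna_id" %in% names(df) ||
      !("mirna_seq" %in% names(df) || all(c("start", "end") %in% names(df))))
    ml_stop("annotations need premirna_id plus mirna_seq or start,end columns",
            "mirlocate_data_error")
  df
}

provenance_header <- function(seed = NULL, engine = NULL, extra = NULL) {
  c(sprintf("mirlocate %s", as.character(utils::packageVersion("mirlocate"))),
    sprintf("schema=%s", SCHEMA_VERSION),
    if (!is.null(seed)) sprintf("seed=%s", seed),
    if (!is.null(engine)) sprintf("engine=%s", engine_label(engine)),
    extra)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a feature table as TSV
#'
#' Columns `sample_id`, `label`, then the 440 schema-ordered features; the
#' schema version rides in a `#schema=` comment line.
#'
#' @param dataset a `mirna_dataset`.
#' @param path file path.
#' @export
write_features <- function(dataset, path) {
  df <- cbind(
    data.frame(sample_id = sprintf("%s:%d-%d", dataset$info$premirna_id,
                                   dataset$info$start, dataset$info$end),
               label = dataset$info$label, stringsAsFactors = FALSE),
    as.data.frame(dataset$x))
  write_tsv_with_header(df, path,
                        provenance_header(seed = dataset$seed,
                                          extra = sprintf("rpns=1:%d", dataset$rpns)))
}

read_table_skip_comments <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
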