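#' Read / write feature-by-sample matrices as TSV
#'
#' The on-disk convention is a header line with `feature_id` followed by one
#' column per sample.
#'
#' @param path file path.
#' @return numeric matrix with feature row names and sample column names.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_tsv
#' @param m matrix to write.
#' @param id_name name for the feature-id column.
#' @export
write_matrix_tsv <- function(m, path, id_name = "feature_id") {
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  df <- data.frame(ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype (or any rectangular) table as TSV
#' @param path file path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname read_table_tsv
#' @param df data.frame to write.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a SUPPA-style ioe event catalog
#'
#' Tab-separated with a header line; columns seqname, gene_id, event_id,
#' inclusion transcripts (comma-joined), total transcripts (comma-joined).
#' The event type is parsed from the event id (`gene;TYPE:rest`).
#'
#' @param path path to the .ioe file.
#' @return data.frame with columns seqname, gene_id, event_id, event_type,
#'   inclusion_transcripts, total_transcripts.
#' @export
read_ioe <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df) <- c("seqname", "gene_id", "event_id",
                 "inclusion_transcripts", "total_transcripts")[seq_len(ncol(df))]
  df$event_type <- sub("^[^;]*;([A-Z0-9]+):.*$", "\\1", df$event_id)
  .validate_events(df)
  df[, c("seqname", "gene_id", "event_id", "event_type",
         "inclusion_transcripts", "total_transcripts")]
}

#' @rdname read_ioe
#' @param events event catalog data.frame.
#' @export
write_ioe <- function(events, path) {
  out <- data.frame(seqname = events$seqname, gene_id = events$gene_id,
                    event_id = events$event_id,
                    alternative_transcripts = events$inclusion_transcripts,
                    total_transcripts = events$total_transcripts,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.split_ids <- function(x) strsplit(x, ",", fixed = TRUE)

.validate_events <- function(events) {
  incl <- .split_ids(events$inclusion_transcripts)
  tot <- .split_ids(events$total_transcripts)
  for (i in seq_len(nrow(events))) {
    if (length(incl[[i]]) == 0 || !nzchar(incl[[i]][1]))
      stop("event ", events$event_id[i], " has an empty inclusion set")
    if (!all(incl[[i]] %in% tot[[i]]))
      stop("event ", events$event_id[i],
           ": inclusion transcripts not all contained in the total set")
    if (length(setdiff(tot[[i]], incl[[i]])) == 0)
      stop("event ", events$event_id[i],
           ": total set must contain at least one exclusion transcript")
  }
  invisible(events)
}

#' Read gene sets in GMT format
#'
#' Tab-separated, one set per line: name, description, then member ids.
#' Duplicate members within a set are dropped.
#'
#' @param path path to the .gmt file.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(fld) {
    if (length(fld) < 3) stop("malformed GMT line: ", fld[1])
    unique(fld[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' @rdname read_gmt
#' @param sets named list of member-id vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
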