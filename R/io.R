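#' Read a FASTA file
#'
#' Reads a plain or gzip-compressed multi-FASTA file, preserving record
#' order and letter case (soft-masked lowercase runs are kept and
#' flagged). Identifiers are taken up to the first whitespace in the
#' header line.
#'
#' @param path FASTA file path.
#' @return A data frame with columns `id`, `seq` (case preserved) and
#'   `softmasked` (record contains lowercase letters).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  head_lines <- readLines(con, n = 50L)
  close(con)
  first <- head_lines[nzchar(trimws(head_lines))]
  if (length(first) > 0L && !startsWith(first[1L], ">"))
    stop("malformed FASTA at record 1: expected '>' header in ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e)
                  stop("malformed FASTA file ", path, ": ",
                       conditionMessage(e), call. = FALSE))
  if (length(x) == 0L)
    return(data.frame(id = character(0), seq = character(0),
                      softmasked = logical(0), stringsAsFactors = FALSE))
  ids <- sub("[[:space:]].*$", "", names(x))
  seqs <- unname(as.character(x))
  bad <- grepl("[^A-Za-z*.-]", seqs)
  if (any(bad))
    stop("malformed FASTA at record ", which(bad)[1L],
         ": non-sequence characters in ", path)
  data.frame(id = ids, seq = seqs, softmasked = grepl("[a-z]", seqs),
             stringsAsFactors = FALSE)
}

write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs))
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  out <- character(0)
  for (i in seq_along(seqs)) {
    out <- c(out, paste0(">", ids[i]))
    s <- seqs[[i]]
    if (nchar(s) > 0L) {
      starts <- seq.int(1L, nchar(s), by = width)
      out <- c(out, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
    }
  }
  writeLines(out, path)
  invisible(path)
}

# fixed column order of the user-facing hit report (1-based inclusive
# coordinates)
HIT_RECORD_COLUMNS <- c("sequence_id", "start", "end", "strand",
                        "matched_nt", "tag_aa", "mismatches",
                        "edited_positions", "filter_pass",
                        "filter_reasons", "stop_free_span_aa",
                        "best_reference", "best_score")

empty_hit_records <- function() {
  data.frame(sequence_id = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             matched_nt = character(0), tag_aa = character(0),
             mismatches = integer(0), edited_positions = character(0),
             filter_pass = logical(0), filter_reasons = character(0),
             stop_free_span_aa = integer(0),
             best_reference = character(0), best_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write hit records as TSV
#'
#' Tab-separated report with a fixed column order and a header row;
#' coordinates are 1-based inclusive. An empty record set yields a
#' header-only file.
#'
#' @param records Hit-record data frame (see [run_pipeline()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(HIT_RECORD_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  write.table(records[, HIT_RECORD_COLUMNS, drop = FALSE], path,
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read back a TSV hit report
#'
#' @param path TSV file written by [write_hits_tsv()].
#' @return Hit-record data frame with the original column types.
#' @export
read_hits_tsv <- function(path) {
  cls <- c(sequence_id = "character", start = "integer", end = "integer",
           strand = "character", matched_nt = "character",
           tag_aa = "character", mismatches = "integer",
           edited_positions = "character", filter_pass = "logical",
           filter_reasons = "character", stop_free_span_aa = "integer",
           best_reference = "character", best_score = "numeric")
  read.delim(path, colClasses = unname(cls[HIT_RECORD_COLUMNS]),
             stringsAsFactors = FALSE)
}

#' Write hit records as GFF3
#'
#' One `sequence_feature` line per record; the GFF score column carries
#' the mismatch count and the attributes carry the translated tag and
#' the filter verdict. Coordinates are 1-based inclusive per the GFF3
#' convention.
#'
#' @inheritParams write_hits_tsv
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(records, path) {
  stopifnot(is.data.frame(records))
  lines <- "##gff-version 3"
  if (nrow(records) > 0L) {
    attrs <- sprintf("ID=hit%d;tag_aa=%s;filter_pass=%s%s",
                     seq_len(nrow(records)),
                     records$tag_aa,
                     ifelse(records$filter_pass, "true", "false"),
                     ifelse(nzchar(records$edited_positions) &
                              !is.na(records$edited_positions),
                            paste0(";edited_positions=",
                                   records$edited_positions), ""))
    lines <- c(lines, sprintf("%s\ttagscan\tsequence_feature\t%d\t%d\t%d\t%s\t.\t%s",
                              records$sequence_id, records$start,
                              records$end, records$mismatches,
                              records$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}
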