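#' Run the full tag-search pipeline
#'
#' Chains the whole method: compile the protein tag into a degenerate
#' nucleotide pattern, scan every input sequence on the requested
#' strands, extract and translate a candidate window around each hit,
#' apply the wildcard residue filter and the stop-free-span screen,
#' and (optionally) rank each candidate against reference proteins by
#' Smith-Waterman local alignment.
#'
#' @param fasta Input sequences: a FASTA path (plain or gzip), a named
#'   character vector of sequences, or a data frame with `id` and
#'   `seq` columns as returned by [read_fasta()].
#' @param tag A tag string (see [parse_tag()]) or a `tag_spec`.
#' @param references Optional reference proteins: a FASTA path or a
#'   named character vector of amino-acid sequences.
#' @param config A [scan_config()].
#' @param window_nt Candidate window size (default 1200 nt).
#' @param allowed_set Wildcard filter set; default [FILTER_ALLOWED].
#' @param code A [genetic_code()].
#' @param matrix,gap_open,gap_extend Alignment parameters for the
#'   reference ranking; defaults BLOSUM62, 11, 1.
#' @return A hit-record data frame (one row per hit, 1-based inclusive
#'   coordinates) with columns `sequence_id`, `start`, `end`, `strand`,
#'   `matched_nt`, `tag_aa`, `mismatches`, `edited_positions`,
#'   `filter_pass`, `filter_reasons`, `stop_free_span_aa`,
#'   `best_reference`, `best_score`, sorted by (sequence_id, start,
#'   strand).
#' @examples
#' seqs <- c(chr1 = "CCACTGCTTGTGGATAGTAAATTAGGT")  # encodes PLLVDSKLG
#' run_pipeline(seqs, "P-XXX-D-X-K-X-G")[, c("start", "end", "tag_aa",
#'                                           "filter_pass")]
#' @export
run_pipeline <- function(fasta, tag, references = NULL,
                         config = scan_config(), window_nt = 1200L,
                         allowed_set = FILTER_ALLOWED,
                         code = genetic_code(), matrix = NULL,
                         gap_open = 11, gap_extend = 1) {
  spec <- if (inherits(tag, "tag_spec")) tag else parse_tag(tag)
  pattern <- reverse_translate(spec, code)

  recs <- if (is.data.frame(fasta)) {
    stopifnot(all(c("id", "seq") %in% names(fasta)))
    fasta
  } else if (is.character(fasta) && length(fasta) == 1L &&
             is.null(names(fasta)) && file.exists(fasta)) {
    read_fasta(fasta)
  } else if (is.character(fasta)) {
    data.frame(id = names(fasta) %||% paste0("seq", seq_along(fasta)),
               seq = unname(fasta), stringsAsFactors = FALSE)
  } else {
    stop("unsupported 'fasta' input")
  }

  refs <- NULL
  if (!is.null(references)) {
    refs <- if (is.character(references) && length(references) == 1L &&
                file.exists(references)) {
      r <- read_fasta(references)
      setNames(toupper(r$seq), r$id)
    } else {
      stopifnot(is.character(references), !is.null(names(references)))
      toupper(references)
    }
    if (is.null(matrix)) matrix <- blosum62()
  }

  rows <- vector("list", 0L)
  for (i in seq_len(nrow(recs))) {
    hits <- scan_sequence(recs$seq[i], pattern, config,
                          sequence_id = recs$id[i])
    for (h in seq_len(nrow(hits))) {
      hit <- hits[h, ]
      cand <- translate_window(
        extract_candidate(recs$seq[i], hit, window_nt, code))
      verdict <- filter_wildcards(cand, spec, allowed_set)
      sf <- stop_free_span(cand)
      best_ref <- NA_character_
      best_score <- NA_real_
      if (!is.null(refs) && length(refs) > 0L) {
        scores <- vapply(refs, function(r)
          smith_waterman(cand$protein, r, matrix, gap_open,
                         gap_extend)$score, numeric(1))
        k <- which.max(scores)
        best_ref <- names(refs)[k]
        best_score <- unname(scores[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = hit$sequence_id,
        start = hit$start + 1L,
        end = hit$end,
        strand = hit$strand,
        matched_nt = hit$matched_nt,
        tag_aa = cand$tag_aa,
        mismatches = hit$mismatch_count,
        edited_positions = hit$edited_positions,
        filter_pass = verdict$pass,
        filter_reasons = paste(verdict$reasons, collapse = "; "),
        stop_free_span_aa = sf$span_aa,
        best_reference = best_ref,
        best_score = best_score,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_hit_records())
  out <- do.call(rbind, rows)
  out <- out[order(out$sequence_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
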