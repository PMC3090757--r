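#' Extract a candidate gene region around a hit
#'
#' Cuts a window of about `window_nt` nucleotides centred on the
#' matched tag, the classical post-processing step before translation.
#' Flank lengths are rounded down to codon multiples so that the
#' reading frame anchored at the first box is preserved, and clamped at
#' the sequence ends with truncation flags. Minus-strand hits yield the
#' reverse-complement (coding-strand) window; truncation flags are
#' reported in the coding-strand orientation.
#'
#' @param seq The full nucleotide sequence the hit was found in.
#' @param hit One row of a `tag_hits` data frame (or an equivalent
#'   list with `start`, `end`, `strand` in 0-based half-open forward
#'   coordinates).
#' @param window_nt Target window size in nt; default 1200, the
#'   conventional extraction width around the inositol-binding tag
#'   (about 400 codons).
#' @param code A [genetic_code()] (stored for later translation).
#' @return A `candidate_region` object with the window, its forward
#'   coordinates, flank lengths and truncation flags. Translation
#'   fields are filled in by [translate_window()].
#' @export
extract_candidate <- function(seq, hit, window_nt = 1200L,
                              code = genetic_code()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  hit <- as.list(hit)
  L <- nchar(seq)
  start <- as.integer(hit$start)
  end <- as.integer(hit$end)
  if (is.na(start) || is.na(end) || start < 0L || end > L || end <= start)
    stop("hit coordinates outside sequence")
  span <- end - start
  extra <- max(0L, as.integer(window_nt) - span)
  # left flank gets the floor half rounded to a codon multiple; the
  # remainder (also codon-rounded) goes right
  left_des <- 3L * (extra %/% 6L)
  right_des <- 3L * ((extra - left_des) %/% 3L)
  if (identical(hit$strand, "-")) {
    avail_left <- L - end   # 5' flank of the coding strand
    avail_right <- start
  } else {
    avail_left <- start
    avail_right <- L - end
  }
  left <- min(left_des, 3L * (avail_left %/% 3L))
  right <- min(right_des, 3L * (avail_right %/% 3L))
  if (identical(hit$strand, "-")) {
    ws <- start - right; we <- end + left
  } else {
    ws <- start - left; we <- end + right
  }
  w <- substr(seq, ws + 1L, we)
  if (identical(hit$strand, "-")) w <- revcomp_chr(w)
  structure(list(hit = hit,
                 window_nt = toupper(w),
                 window_start = ws,
                 window_end = we,
                 flank_left_nt = left,
                 flank_right_nt = right,
                 truncated_left = left < left_des,
                 truncated_right = right < right_des,
                 code = code,
                 protein = NULL,
                 tag_aa = NULL,
                 tag_offset_aa = NULL),
            class = "candidate_region")
}

#' Translate a candidate window in the tag-anchored frame
#'
#' Single-frame translation starting at the window's first codon; since
#' flanks are codon multiples this frame is anchored at the tag's first
#' box. Stop codons are rendered `"*"`. The translated tag
#' (`tag_aa`) and its offset within the protein are recorded.
#'
#' @param candidate A `candidate_region` from [extract_candidate()].
#' @param code A [genetic_code()]; defaults to the one stored at
#'   extraction.
#' @return The candidate with `protein`, `tag_aa` and `tag_offset_aa`
#'   filled in.
#' @export
translate_window <- function(candidate, code = NULL) {
  stopifnot(inherits(candidate, "candidate_region"))
  code <- code %||% candidate$code
  if (nchar(candidate$window_nt) < 3L)
    stop("window shorter than one codon")
  prot <- translate_nt(candidate$window_nt, code)
  off <- candidate$flank_left_nt %/% 3L
  taglen_aa <- (candidate$hit$end - candidate$hit$start) %/% 3L
  candidate$protein <- prot
  candidate$tag_offset_aa <- off
  candidate$tag_aa <- substr(prot, off + 1L, off + taglen_aa)
  candidate
}

#' Screen a candidate tag by residue composition
#'
#' The decisive post-scan filter: a candidate passes if every fixed
#' position of the translated tag carries exactly the specified residue
#' and every wildcard position carries a residue from the allowed set
#' (by default [FILTER_ALLOWED], the small/apolar residues compatible
#' with the inositol-binding pocket). Candidates whose fixed positions
#' deviate -- possible under mismatch or editing-tolerant matching --
#' fail with explicit reasons rather than being dropped.
#'
#' A wildcard position whose `tag_spec` carries its own restricted
#' allowed set is checked against that set instead.
#'
#' @param candidate A translated `candidate_region`, or a plain
#'   amino-acid string of the tag.
#' @param spec The `tag_spec` the pattern was compiled from.
#' @param allowed_set Residues allowed at unrestricted wildcard
#'   positions.
#' @return A list with `pass` (logical) and `reasons` (character
#'   vector, empty when passing).
#' @examples
#' spec <- parse_tag("P-XXX-D-X-K-X-G")
#' filter_wildcards("PLLVDSKLG", spec)$pass   # TRUE
#' filter_wildcards("PVGTDRKGG", spec)$pass   # FALSE (R not allowed)
#' @export
filter_wildcards <- function(candidate, spec, allowed_set = FILTER_ALLOWED) {
  stopifnot(inherits(spec, "tag_spec"))
  tag_aa <- if (inherits(candidate, "candidate_region")) {
    if (is.null(candidate$tag_aa))
      stop("candidate has not been translated; call translate_window() first")
    candidate$tag_aa
  } else {
    stopifnot(is.character(candidate), length(candidate) == 1L)
    toupper(candidate)
  }
  n <- tag_length(spec)
  if (nchar(tag_aa) != n)
    return(list(pass = FALSE,
                reasons = sprintf(
                  "translated tag has %d residues, expected %d",
                  nchar(tag_aa), n)))
  chars <- strsplit(tag_aa, "", fixed = TRUE)[[1]]
  reasons <- character(0)
  for (i in seq_len(n)) {
    p <- spec$positions[[i]]
    ch <- chars[i]
    if (p$kind == "fixed") {
      if (ch != p$residue)
        reasons <- c(reasons, sprintf(
          "position %d: '%s' differs from fixed residue '%s'",
          i, ch, p$residue))
    } else {
      alw <- if (length(p$allowed) < length(AMINO_ACIDS)) p$allowed
             else allowed_set
      if (!(ch %in% alw))
        reasons <- c(reasons, sprintf(
          "position %d: wildcard residue '%s' not in allowed set {%s}",
          i, ch, paste(alw, collapse = ",")))
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Longest stop-free run containing the tag
#'
#' An open-reading-frame plausibility screen: the length of the longest
#' run of non-stop residues in the translated window that fully
#' contains the tag. Runs are delimited by `"*"`; the run containing
#' the tag is unique, and ties among equally long runs are irrelevant
#' because only the containing run is reported. If the tag region
#' itself contains a stop codon the span is undefined and the candidate
#' is flagged as failed.
#'
#' @param candidate A translated `candidate_region`.
#' @return A list with `span_aa` (integer, `NA` if undefined),
#'   `bounds` (1-based inclusive residue interval of the run, or
#'   `NULL`) and `tag_contains_stop` (logical).
#' @export
stop_free_span <- function(candidate) {
  stopifnot(inherits(candidate, "candidate_region"))
  if (is.null(candidate$protein))
    stop("candidate has not been translated; call translate_window() first")
  chars <- strsplit(candidate$protein, "", fixed = TRUE)[[1]]
  tl <- nchar(candidate$tag_aa)
  t0 <- candidate$tag_offset_aa + 1L
  t1 <- t0 + tl - 1L
  if (t1 > length(chars) || any(chars[t0:t1] == "*"))
    return(list(span_aa = NA_integer_, bounds = NULL,
                tag_contains_stop = TRUE))
  ok <- chars != "*"
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values & starts <= t0 & ends >= t1)
  list(span_aa = as.integer(r$lengths[i]),
       bounds = c(starts[i], ends[i]),
       tag_contains_stop = FALSE)
}

#' Protein subregion centred on the tag
#'
#' Returns a substring of the candidate protein of (up to)
#' `radius_aa` residues containing the tag, the form in which candidate
#' regions are compared across organisms (e.g. the 50- or 410-residue
#' regions around the consensus). Residues are redistributed to the
#' other side when the tag sits near an end, and the result is clamped
#' to the whole protein when `radius_aa` exceeds it.
#'
#' @param candidate A translated `candidate_region`.
#' @param radius_aa Total width of the subregion in residues.
#' @return A list with `protein` (the substring), `tag_offset_aa`
#'   (0-based offset of the tag within the substring) and
#'   `offset_in_protein_aa` (0-based offset of the substring within the
#'   full protein).
#' @export
subregion <- function(candidate, radius_aa) {
  stopifnot(inherits(candidate, "candidate_region"))
  if (is.null(candidate$protein))
    stop("candidate has not been translated; call translate_window() first")
  n <- nchar(candidate$protein)
  tl <- nchar(candidate$tag_aa)
  t0 <- candidate$tag_offset_aa          # 0-based
  extra <- max(0L, as.integer(radius_aa) - tl)
  left_des <- extra %/% 2L
  right_des <- extra - left_des
  avail_r <- n - (t0 + tl)
  left <- min(left_des, t0)
  right <- min(right_des, avail_r)
  spare <- (left_des - left) + (right_des - right)
  add_r <- min(spare, avail_r - right)
  right <- right + add_r
  left <- min(left + (spare - add_r), t0)
  start0 <- t0 - left
  end0 <- t0 + tl + right                # exclusive
  list(protein = substr(candidate$protein, start0 + 1L, end0),
       tag_offset_aa = left,
       offset_in_protein_aa = start0)
}

#' @export
print.candidate_region <- function(x, ...) {
  cat(sprintf("Candidate region %s:%d-%d (%s)\n",
              x$hit$sequence_id %||% "seq", x$window_start, x$window_end,
              x$hit$strand))
  cat(sprintf("  window %d nt%s%s\n", nchar(x$window_nt),
              if (x$truncated_left) ", truncated left" else "",
              if (x$truncated_right) ", truncated right" else ""))
  if (!is.null(x$protein))
    cat(sprintf("  tag %s at protein offset %d (protein %d aa)\n",
                x$tag_aa, x$tag_offset_aa, nchar(x$protein)))
  invisible(x)
}
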