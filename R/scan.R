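# bitmask encoding of nucleotides: A=1, C=2, G=4, T=8; IUPAC codes are
# unions of these bits
NT_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L,
             M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
             V = 7L, H = 11L, D = 13L, B = 14L, N = 15L)

set_mask <- function(s) as.integer(sum(NT_MASK[s]))

# encode a character vector of bases as bitmasks; positions that may
# not satisfy any constrained pattern position get mask 0
encode_nt <- function(chars, ambiguous_base_matches = FALSE,
                      include_softmasked = TRUE) {
  up <- toupper(chars)
  m <- NT_MASK[up]
  m[is.na(m)] <- 0L
  if (!ambiguous_base_matches)
    m[!(up %in% c("A", "C", "G", "T"))] <- 0L
  if (!include_softmasked)
    m[chars != up] <- 0L
  as.integer(m)
}

#' Scan configuration
#'
#' Bundles the matching options of the genome scanner.
#'
#' @param max_mismatches Non-negative mismatch budget over constrained
#'   (box) positions; gaps never mismatch. Default 0.
#' @param allow_skips Tolerate at most one single-nucleotide deletion
#'   per box (counted separately from mismatches). Default `FALSE`.
#' @param allow_swaps Tolerate one exchange of two adjacent boxes,
#'   flagged in the hit. Frame-destroying; default `FALSE`.
#' @param strands `"both"`, `"plus"` or `"minus"`.
#' @param editing An [editing_policy()]; default no editing tolerance.
#' @param ambiguous_base_matches If `TRUE`, IUPAC ambiguity codes in the
#'   subject match a constrained position whenever their base sets
#'   intersect; if `FALSE` (default) only A/C/G/T can match a
#'   constrained position (`N` never matches).
#' @param include_softmasked If `FALSE`, lowercase (soft-masked) bases
#'   never match a constrained position; default `TRUE` (case-folded).
#' @return A `scan_config` object.
#' @export
scan_config <- function(max_mismatches = 0L,
                        allow_skips = FALSE,
                        allow_swaps = FALSE,
                        strands = c("both", "plus", "minus"),
                        editing = editing_policy(),
                        ambiguous_base_matches = FALSE,
                        include_softmasked = TRUE) {
  strands <- match.arg(strands)
  max_mismatches <- as.integer(max_mismatches)
  stopifnot(max_mismatches >= 0L, inherits(editing, "editing_policy"),
            is.logical(allow_skips), is.logical(allow_swaps),
            is.logical(ambiguous_base_matches), is.logical(include_softmasked))
  structure(list(max_mismatches = max_mismatches,
                 allow_skips = allow_skips,
                 allow_swaps = allow_swaps,
                 strands = strands,
                 editing = editing,
                 ambiguous_base_matches = ambiguous_base_matches,
                 include_softmasked = include_softmasked),
            class = "scan_config")
}

empty_hits <- function() {
  structure(data.frame(sequence_id = character(0),
                       strand = character(0),
                       start = integer(0),
                       end = integer(0),
                       box_starts = character(0),
                       mismatch_count = integer(0),
                       skip_count = integer(0),
                       swapped = logical(0),
                       matched_nt = character(0),
                       edited_positions = character(0),
                       stringsAsFactors = FALSE),
            class = c("tag_hits", "data.frame"))
}

# one skip deletes one nucleotide from a box; at most one per box
box_skip_variants <- function(sets, allow_skips) {
  v <- list(list(sets = sets, skip = 0L))
  if (allow_skips && length(sets) > 1L) {
    for (j in seq_along(sets))
      v[[length(v) + 1L]] <- list(sets = sets[-j], skip = 1L)
  }
  v
}

# enumerate concrete layouts of the pattern under a config: each layout
# fixes a box order (swaps), a skip choice per box and a gap-length
# combination, and carries flattened constrained-position offsets with
# editing-expanded and base masks
pattern_layouts <- function(pattern, config) {
  validate_pattern(pattern)
  expanded <- apply_editing(pattern, config$editing)
  nb <- length(pattern$boxes)

  orders <- list(list(idx = seq_len(nb), swapped = FALSE))
  if (config$allow_swaps && nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      idx <- seq_len(nb)
      idx[c(i, i + 1L)] <- idx[c(i + 1L, i)]
      orders[[length(orders) + 1L]] <- list(idx = idx, swapped = TRUE)
    }
  }
  gcombos <- gap_combinations(pattern$gaps)

  layouts <- list()
  for (ord in orders) {
    exp_boxes <- expanded$boxes[ord$idx]
    base_boxes <- pattern$boxes[ord$idx]
    skip_vars <- lapply(exp_boxes, function(b)
      box_skip_variants(b$sets, config$allow_skips))
    base_skip_vars <- lapply(base_boxes, function(b)
      box_skip_variants(b$sets, config$allow_skips))
    skip_choice <- lapply(skip_vars, seq_along)
    skip_grid <- expand.grid(rev(skip_choice), KEEP.OUT.ATTRS = FALSE)
    skip_grid <- skip_grid[, rev(seq_len(ncol(skip_grid))), drop = FALSE]
    for (si in seq_len(nrow(skip_grid))) {
      choice <- as.integer(skip_grid[si, ])
      sets_list <- lapply(seq_len(nb), function(b) skip_vars[[b]][[choice[b]]])
      base_sets_list <- lapply(seq_len(nb), function(b)
        base_skip_vars[[b]][[choice[b]]]$sets)
      skip_count <- sum(vapply(sets_list, function(v) v$skip, integer(1)))
      for (g in gcombos) {
        offsets <- integer(0); masks <- integer(0); base_masks <- integer(0)
        box_starts <- integer(nb)
        pos <- 0L
        for (b in seq_len(nb)) {
          box_starts[b] <- pos
          bs <- sets_list[[b]]$sets
          bb <- base_sets_list[[b]]
          for (j in seq_along(bs)) {
            offsets <- c(offsets, pos)
            masks <- c(masks, set_mask(bs[[j]]))
            base_masks <- c(base_masks, set_mask(bb[[j]]))
            pos <- pos + 1L
          }
          if (b < nb) pos <- pos + g[b]
        }
        layouts[[length(layouts) + 1L]] <-
          list(offsets = offsets, masks = masks, base_masks = base_masks,
               span = pos, box_starts = box_starts,
               skip_count = skip_count, swapped = ord$swapped)
      }
    }
  }
  layouts
}

# order hits canonically and drop exact duplicates (same sequence_id,
# start, end, strand), keeping the variant with the fewest mismatches,
# then fewest skips, then earliest enumeration
finalize_hits <- function(df) {
  if (nrow(df) == 0L) {
    df$.layout <- NULL
    class(df) <- c("tag_hits", "data.frame")
    rownames(df) <- NULL
    return(df)
  }
  ord <- order(df$mismatch_count, df$skip_count, df$.layout)
  df <- df[ord, , drop = FALSE]
  key <- paste(df$sequence_id, df$start, df$end, df$strand, sep = "\r")
  df <- df[!duplicated(key), , drop = FALSE]
  df$.layout <- NULL
  df <- df[order(df$start, df$strand, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("tag_hits", "data.frame")
  df
}

#' Scan a nucleotide sequence for a compiled tag pattern
#'
#' Finds every placement of `pattern` in `seq` satisfying the
#' configuration, enumerating all gap lengths within each gap interval,
#' on the requested strands. Minus-strand matches are located on the
#' reverse complement and reported in forward-strand coordinates
#' (0-based, half-open). Overlapping and nested hits are all reported;
#' exact duplicates (same start, end, strand) are reported once.
#' [brute_force_scan()] is the reference semantics.
#'
#' @param seq Nucleotide string (IUPAC letters allowed).
#' @param pattern An `nt_pattern` from [reverse_translate()].
#' @param config A [scan_config()].
#' @param sequence_id Identifier attached to hits.
#' @return A `tag_hits` data frame sorted by (start, strand) with
#'   columns `sequence_id`, `strand`, `start`, `end`, `box_starts`
#'   (comma-separated offsets of box starts within the match,
#'   strand-oriented), `mismatch_count`, `skip_count`, `swapped`,
#'   `matched_nt` (strand-oriented) and `edited_positions`
#'   (comma-separated match offsets that required the editing
#'   expansion; empty when none).
#' @examples
#' pat <- reverse_translate(parse_tag("P-XXX-D-X-K-X-G"))
#' scan_sequence("CCAGTTGGAACTGATCGTAAAGGCGGT", pat, scan_config())
#' @export
scan_sequence <- function(seq, pattern, config = scan_config(),
                          sequence_id = "seq") {
  validate_pattern(pattern)
  stopifnot(is.character(seq), length(seq) == 1L,
            inherits(config, "scan_config"))
  total_positions <- sum(vapply(pattern$boxes, function(b) length(b$sets),
                                integer(1)))
  if (config$max_mismatches > total_positions)
    stop("mismatch budget exceeds the number of constrained positions")
  L <- nchar(seq)
  layouts <- pattern_layouts(pattern, config)
  min_span <- min(vapply(layouts, function(l) l$span, integer(1)))
  strands <- switch(config$strands,
                    both = c("+", "-"), plus = "+", minus = "-")
  if (L < min_span) return(empty_hits())

  pieces <- list()
  layout_counter <- 0L
  for (strand in strands) {
    oriented <- if (strand == "+") seq else revcomp_chr(seq)
    chars <- strsplit(oriented, "", fixed = TRUE)[[1]]
    codes <- encode_nt(chars, config$ambiguous_base_matches,
                       config$include_softmasked)
    up <- toupper(oriented)
    for (li in seq_along(layouts)) {
      lay <- layouts[[li]]
      layout_counter <- layout_counter + 1L
      ns <- L - lay$span + 1L
      if (ns < 1L) next
      idx <- seq_len(ns)
      mism <- integer(ns)
      for (k in seq_along(lay$offsets)) {
        ok <- bitwAnd(codes[idx + lay$offsets[k]], lay$masks[k]) != 0L
        mism <- mism + !ok
      }
      keep <- which(mism <= config$max_mismatches)
      if (length(keep) == 0L) next

      edited <- character(length(keep))
      diffk <- which(lay$masks != lay$base_masks)
      if (length(diffk) > 0L) {
        for (h in seq_along(keep)) {
          offs <- lay$offsets[diffk]
          cc <- codes[keep[h] + offs]
          ed <- offs[bitwAnd(cc, lay$base_masks[diffk]) == 0L &
                       bitwAnd(cc, lay$masks[diffk]) != 0L]
          edited[h] <- paste(ed, collapse = ",")
        }
      }
      if (strand == "+") {
        fstart <- keep - 1L
        fend <- fstart + lay$span
      } else {
        fstart <- L - (keep - 1L + lay$span)
        fend <- L - (keep - 1L)
      }
      pieces[[length(pieces) + 1L]] <- data.frame(
        sequence_id = sequence_id,
        strand = strand,
        start = fstart,
        end = fend,
        box_starts = paste(lay$box_starts, collapse = ","),
        mismatch_count = mism[keep],
        skip_count = lay$skip_count,
        swapped = lay$swapped,
        matched_nt = substring(up, keep, keep + lay$span - 1L),
        edited_positions = edited,
        .layout = layout_counter,
        stringsAsFactors = FALSE)
    }
  }
  if (length(pieces) == 0L) return(empty_hits())
  finalize_hits(do.call(rbind, pieces))
}

#' Scan every record of a FASTA file
#'
#' Applies [scan_sequence()] to each record of a (possibly
#' gzip-compressed) multi-FASTA file, in file order, and concatenates
#' the hits. Record identifiers are taken up to the first whitespace.
#'
#' @param path FASTA file, plain or gzip.
#' @inheritParams scan_sequence
#' @return A `tag_hits` data frame.
#' @export
scan_fasta <- function(path, pattern, config = scan_config()) {
  recs <- read_fasta(path)
  if (nrow(recs) == 0L) return(empty_hits())
  out <- lapply(seq_len(nrow(recs)), function(i)
    scan_sequence(recs$seq[i], pattern, config, sequence_id = recs$id[i]))
  res <- do.call(rbind, out)
  class(res) <- c("tag_hits", "data.frame")
  rownames(res) <- NULL
  res
}
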