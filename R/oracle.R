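# IUPAC letter -> set of concrete bases it can stand for
IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                   M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                   S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                   V = c("A", "C", "G"), H = c("A", "C", "T"),
                   D = c("A", "G", "T"), B = c("C", "G", "T"),
                   N = c("A", "C", "G", "T"))

# sentinel marking an unconstrained (gap) position in a flattened
# variant; distinct from a fully degenerate box position, which is
# still constrained (an N never satisfies it under strict matching)
GAP_POS <- NA_character_

is_gap_pos <- function(s) length(s) == 1L && is.na(s[1L])

#' Exhaustive reference scanner
#'
#' A deliberately naive scanner that walks every start position, strand,
#' box order, skip choice and gap-length combination, testing each
#' constrained position by set membership. It defines the semantics of
#' [scan_sequence()] and serves as the independent oracle in the test
#' suite; a guard bound keeps it off large inputs.
#'
#' @inheritParams scan_sequence
#' @param guard Maximum sequence length accepted (default 100 kb).
#' @return A `tag_hits` data frame identical in layout to
#'   [scan_sequence()] output.
#' @export
brute_force_scan <- function(seq, pattern, config = scan_config(),
                             sequence_id = "seq", guard = 100000L) {
  validate_pattern(pattern)
  stopifnot(inherits(config, "scan_config"))
  L <- nchar(seq)
  if (L > guard) stop("sequence exceeds the brute-force guard bound (",
                      guard, " nt)")
  expanded <- apply_editing(pattern, config$editing)
  nb <- length(pattern$boxes)

  # enumerate concrete variants: (box order) x (skip choices) x (gaps);
  # each variant is a list of per-position constraint sets with the gap
  # sentinel at unconstrained positions
  variants <- list()
  orders <- list(list(idx = seq_len(nb), swapped = FALSE))
  if (config$allow_swaps && nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      idx <- seq_len(nb)
      idx[c(i, i + 1L)] <- idx[c(i + 1L, i)]
      orders[[length(orders) + 1L]] <- list(idx = idx, swapped = TRUE)
    }
  }

  add_variant <- function(ord, skip_sets, base_sets, skips, gaps) {
    sets <- list(); base <- list(); box_starts <- integer(nb)
    for (b in seq_len(nb)) {
      box_starts[b] <- length(sets)
      for (j in seq_along(skip_sets[[b]])) {
        sets[[length(sets) + 1L]] <- skip_sets[[b]][[j]]
        base[[length(base) + 1L]] <- base_sets[[b]][[j]]
      }
      if (b < nb && gaps[b] > 0L) {
        for (g in seq_len(gaps[b])) {
          sets[[length(sets) + 1L]] <- GAP_POS
          base[[length(base) + 1L]] <- GAP_POS
        }
      }
    }
    variants[[length(variants) + 1L]] <<-
      list(sets = sets, base = base, span = length(sets),
           box_starts = box_starts, skip_count = sum(skips),
           swapped = ord$swapped)
  }

  recurse_gaps <- function(ord, skip_sets, base_sets, skips, i, acc) {
    if (i > nrow(pattern$gaps)) {
      add_variant(ord, skip_sets, base_sets, skips, acc)
      return(invisible(NULL))
    }
    for (g in seq.int(pattern$gaps$min_nt[i], pattern$gaps$max_nt[i]))
      recurse_gaps(ord, skip_sets, base_sets, skips, i + 1L, c(acc, g))
  }
  recurse_skips <- function(ord, b, skip_sets, base_sets, skips) {
    if (b > nb) {
      recurse_gaps(ord, skip_sets, base_sets, skips, 1L, integer(0))
      return(invisible(NULL))
    }
    ebox <- expanded$boxes[[ord$idx[b]]]$sets
    bbox <- pattern$boxes[[ord$idx[b]]]$sets
    recurse_skips(ord, b + 1L, c(skip_sets, list(ebox)),
                  c(base_sets, list(bbox)), c(skips, 0L))
    if (config$allow_skips && length(ebox) > 1L) {
      for (j in seq_along(ebox))
        recurse_skips(ord, b + 1L, c(skip_sets, list(ebox[-j])),
                      c(base_sets, list(bbox[-j])), c(skips, 1L))
    }
  }
  for (ord in orders) recurse_skips(ord, 1L, list(), list(), integer(0))

  # per-variant lookup tables for the strict (non-ambiguous) path:
  # constrained offsets and logical membership over A,C,G,T
  bases4 <- c("A", "C", "G", "T")
  for (vi in seq_along(variants)) {
    v <- variants[[vi]]
    cpos <- which(!vapply(v$sets, is_gap_pos, logical(1)))
    variants[[vi]]$cpos <- cpos
    variants[[vi]]$setlog <- lapply(v$sets[cpos], function(s) bases4 %in% s)
    variants[[vi]]$baselog <- lapply(v$base[cpos], function(s) bases4 %in% s)
  }

  strands <- switch(config$strands,
                    both = c("+", "-"), plus = "+", minus = "-")
  rows <- list()
  vcount <- 0L
  max_mm <- config$max_mismatches
  for (strand in strands) {
    oriented <- if (strand == "+") seq else revcomp_chr(seq)
    raw <- strsplit(oriented, "", fixed = TRUE)[[1]]
    up <- toupper(raw)
    soft <- raw != up
    ci <- match(up, bases4)
    if (!config$include_softmasked) ci[soft] <- NA_integer_
    for (v in variants) {
      vcount <- vcount + 1L
      if (L < v$span) next
      cpos <- v$cpos
      nk <- length(cpos)
      for (start0 in 0:(L - v$span)) {
        mism <- 0L
        edited <- integer(0)
        ok_all <- TRUE
        if (!config$ambiguous_base_matches) {
          for (k in seq_len(nk)) {
            x <- ci[start0 + cpos[k]]
            if (is.na(x) || !v$setlog[[k]][x]) {
              mism <- mism + 1L
              if (mism > max_mm) { ok_all <- FALSE; break }
            } else if (!v$baselog[[k]][x]) {
              edited <- c(edited, cpos[k] - 1L)
            }
          }
        } else {
          for (k in seq_len(nk)) {
            p <- cpos[k]
            cset <- v$sets[[p]]
            ch <- up[start0 + p]
            if (!config$include_softmasked && soft[start0 + p]) {
              matches <- FALSE
            } else {
              exp_ch <- IUPAC_SETS[[ch]]
              matches <- !is.null(exp_ch) &&
                length(intersect(exp_ch, cset)) > 0L
            }
            if (!matches) {
              mism <- mism + 1L
              if (mism > max_mm) { ok_all <- FALSE; break }
            } else if (length(intersect(IUPAC_SETS[[ch]] %||% character(0),
                                        v$base[[p]])) == 0L) {
              edited <- c(edited, p - 1L)
            }
          }
        }
        if (!ok_all) next
        if (strand == "+") {
          fs <- start0; fe <- start0 + v$span
        } else {
          fs <- L - (start0 + v$span); fe <- L - start0
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = sequence_id, strand = strand,
          start = fs, end = fe,
          box_starts = paste(v$box_starts, collapse = ","),
          mismatch_count = mism, skip_count = v$skip_count,
          swapped = v$swapped,
          matched_nt = paste(up[(start0 + 1L):(start0 + v$span)],
                             collapse = ""),
          edited_positions = paste(edited, collapse = ","),
          .layout = vcount,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(empty_hits())
  finalize_hits(do.call(rbind, rows))
}
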