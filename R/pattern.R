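#' RNA-editing policy for pattern matching
#'
#' In plant mitochondria the most frequent RNA editing event converts a
#' genomic cytidine into uridine in the transcript (C-to-U). A gene
#' encoded in edited form therefore shows `C` in the genome where the
#' functional mRNA -- and hence the reverse-translated tag pattern --
#' expects `T`. `forward_CtoU` widens every pattern position that admits
#' `T` to also admit `C`; `reverse_UtoC` is the converse relaxation
#' (positions admitting `C` also admit `T`).
#'
#' With both flags off the policy is the identity: applying it leaves
#' any pattern unchanged.
#'
#' @param forward_CtoU logical; tolerate genomic C where the tag expects T.
#' @param reverse_UtoC logical; tolerate genomic T where the tag expects C.
#' @return An `editing_policy` object.
#' @export
editing_policy <- function(forward_CtoU = FALSE, reverse_UtoC = FALSE) {
  stopifnot(is.logical(forward_CtoU), length(forward_CtoU) == 1L,
            is.logical(reverse_UtoC), length(reverse_UtoC) == 1L)
  structure(list(forward_CtoU = forward_CtoU, reverse_UtoC = reverse_UtoC),
            class = "editing_policy")
}

#' Compile a protein tag into a degenerate nucleotide pattern
#'
#' Reverse-translates a [parse_tag()] specification under a genetic
#' code. Each fixed residue becomes a 3-nt *box* whose per-position
#' nucleotide sets are the union of the residue's synonymous codons
#' (positions restricted to a single nucleotide are flagged *anchored*).
#' Maximal runs of wildcard residues between boxes become fixed-length
#' *gaps* of 3 nt per wildcard, preserving the reading frame. The
#' inositol-binding tag P-XXX-D-X-K-X-G compiles to
#' `CC{T,C,A,G} ---------- GA{T,C} --- AA{A,G} --- GG{T,C,A,G}` with gap
#' lengths 9, 3, 3.
#'
#' Wildcards before the first or after the last fixed residue do not
#' constrain matching; their lengths are recorded as `lead_nt` /
#' `trail_nt` metadata.
#'
#' @param spec A `tag_spec`.
#' @param code A [genetic_code()].
#' @return An `nt_pattern` object with elements `boxes` (each with
#'   `sets`, a list of per-position nucleotide sets, `anchor` flags,
#'   `residue` and `aa_index`), `gaps` (data frame of `min_nt`,
#'   `max_nt`), `lead_nt`, `trail_nt` and the source `tag`.
#' @examples
#' pat <- reverse_translate(parse_tag("P-XXX-D-X-K-X-G"))
#' format(pat)
#' @export
reverse_translate <- function(spec, code = genetic_code()) {
  stopifnot(inherits(spec, "tag_spec"), inherits(code, "genetic_code"))
  fams <- codon_families(code)
  boxes <- list()
  gap_nt <- integer(0)
  pending <- 0L
  lead_nt <- 0L
  for (i in seq_along(spec$positions)) {
    p <- spec$positions[[i]]
    if (p$kind == "wildcard") {
      pending <- pending + 3L
      next
    }
    codons <- fams[[p$residue]]
    if (is.null(codons) || length(codons) == 0L)
      stop("no codons for residue ", p$residue, " under code table ", code$id)
    sets <- lapply(1:3, function(j) sort_nt(unique(substr(codons, j, j))))
    box <- list(sets = sets,
                anchor = vapply(sets, function(s) length(s) == 1L, logical(1)),
                residue = p$residue,
                aa_index = i)
    if (length(boxes) == 0L) lead_nt <- pending else gap_nt <- c(gap_nt, pending)
    boxes[[length(boxes) + 1L]] <- box
    pending <- 0L
  }
  structure(list(boxes = boxes,
                 gaps = data.frame(min_nt = gap_nt, max_nt = gap_nt),
                 lead_nt = lead_nt,
                 trail_nt = pending,
                 tag = spec),
            class = "nt_pattern")
}

validate_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "nt_pattern"))
  if (length(pattern$boxes) == 0L) stop("pattern has no boxes")
  if (nrow(pattern$gaps) != length(pattern$boxes) - 1L)
    stop("pattern must have one gap interval between consecutive boxes")
  for (b in pattern$boxes) {
    if (length(b$sets) < 3L) stop("box shorter than 3 nt")
    for (s in b$sets)
      if (length(s) == 0L || !all(s %in% c("A", "C", "G", "T")))
        stop("box position set must be a non-empty subset of {A,C,G,T}")
  }
  if (any(pattern$gaps$min_nt < 0L) ||
      any(pattern$gaps$max_nt < pattern$gaps$min_nt))
    stop("invalid gap interval")
  invisible(pattern)
}

#' Total span of a pattern in nucleotides
#'
#' Defined for fixed gaps only. With `include_flanks = TRUE` (the
#' default) leading/trailing wildcard runs are counted, so the span
#' equals 3 times the number of tag positions.
#'
#' @param pattern An `nt_pattern`.
#' @param include_flanks Count unconstrained leading/trailing wildcards.
#' @return Integer span in nt.
#' @export
pattern_span <- function(pattern, include_flanks = TRUE) {
  validate_pattern(pattern)
  if (any(pattern$gaps$min_nt != pattern$gaps$max_nt))
    stop("span is undefined for variable-length gaps")
  s <- sum(vapply(pattern$boxes, function(b) length(b$sets), integer(1))) +
    sum(pattern$gaps$min_nt)
  if (include_flanks) s <- s + pattern$lead_nt + pattern$trail_nt
  as.integer(s)
}

#' Expand a pattern for RNA-editing-tolerant matching
#'
#' Applies an [editing_policy()] to every box position set; gap
#' intervals and box structure are unchanged. The expansion is monotone:
#' on any sequence, the hits of the input pattern are a subset of the
#' hits of the expanded pattern.
#'
#' @param pattern An `nt_pattern`.
#' @param policy An [editing_policy()].
#' @return The expanded `nt_pattern`.
#' @examples
#' pat <- reverse_translate(parse_tag("F"))   # box TT{T,C}
#' format(apply_editing(pat, editing_policy(forward_CtoU = TRUE)))
#' @export
apply_editing <- function(pattern, policy) {
  validate_pattern(pattern)
  stopifnot(inherits(policy, "editing_policy"))
  if (!policy$forward_CtoU && !policy$reverse_UtoC) return(pattern)
  pattern$boxes <- lapply(pattern$boxes, function(b) {
    b$sets <- lapply(b$sets, function(s) {
      if (policy$forward_CtoU && "T" %in% s) s <- c(s, "C")
      if (policy$reverse_UtoC && "C" %in% s) s <- c(s, "T")
      sort_nt(unique(s))
    })
    b
  })
  pattern
}

#' @export
format.nt_pattern <- function(x, ...) {
  fmt_box <- function(b) {
    paste0(vapply(b$sets, function(s) {
      if (length(s) == 1L) s else paste0("{", paste(s, collapse = ","), "}")
    }, character(1)), collapse = "")
  }
  fmt_gap <- function(mn, mx) {
    if (mn == mx) strrep("-", mn) else sprintf("-[%d..%d]-", mn, mx)
  }
  out <- fmt_box(x$boxes[[1L]])
  if (length(x$boxes) > 1L) {
    for (i in seq_len(nrow(x$gaps))) {
      out <- paste0(out, fmt_gap(x$gaps$min_nt[i], x$gaps$max_nt[i]),
                    fmt_box(x$boxes[[i + 1L]]))
    }
  }
  out
}

#' @export
print.nt_pattern <- function(x, ...) {
  cat("Degenerate nucleotide pattern (", length(x$boxes), "boxes ):\n ",
      format(x), "\n")
  n_anchor <- sum(vapply(x$boxes, function(b) sum(b$anchor), integer(1)))
  cat(sprintf("  %d constrained positions, %d anchored\n",
              sum(vapply(x$boxes, function(b) length(b$sets), integer(1))),
              n_anchor))
  if (x$lead_nt > 0L || x$trail_nt > 0L)
    cat(sprintf("  unconstrained flanks: %d nt leading, %d nt trailing\n",
                x$lead_nt, x$trail_nt))
  invisible(x)
}

#' Per-placement match probability under a uniform background
#'
#' The probability that a single placement of the pattern matches an
#' i.i.d. uniform ACGT sequence: the product over all box positions of
#' (allowed set size)/4. Gaps contribute factor 1. For the compiled
#' inositol-binding tag this is (1/16)(1/32)(1/32)(1/16) = 2^-18.
#'
#' @param pattern An `nt_pattern`.
#' @return Probability in (0, 1].
#' @export
match_probability <- function(pattern) {
  validate_pattern(pattern)
  prod(vapply(pattern$boxes, function(b)
    prod(vapply(b$sets, length, integer(1)) / 4), numeric(1)))
}

#' Expected number of hits on a random background
#'
#' Analytic expectation of the number of enumerated strict-match
#' placements of `pattern` in an i.i.d. uniform sequence of the given
#' length, summed over all gap-length combinations and scanned strands.
#' A sanity statistic for the false-positive rate of a tag. Requires a
#' strict configuration (no mismatches, skips or swaps).
#'
#' @param pattern An `nt_pattern`.
#' @param seq_length Sequence length in nt.
#' @param config A [scan_config()]; only `strands` is consulted, and the
#'   configuration must be strict.
#' @return Expected hit count (real).
#' @export
expected_hit_count <- function(pattern, seq_length, config = scan_config()) {
  validate_pattern(pattern)
  stopifnot(inherits(config, "scan_config"))
  if (config$max_mismatches != 0L || config$allow_skips || config$allow_swaps)
    stop("expected_hit_count requires a strict configuration")
  pattern <- apply_editing(pattern, config$editing)
  p <- match_probability(pattern)
  n_strands <- if (config$strands == "both") 2L else 1L
  box_nt <- sum(vapply(pattern$boxes, function(b) length(b$sets), integer(1)))
  combos <- gap_combinations(pattern$gaps)
  placements <- sum(vapply(combos, function(g)
    max(0, seq_length - (box_nt + sum(g)) + 1), numeric(1)))
  n_strands * placements * p
}

# list of gap-length vectors, lexicographic (first gap varies slowest)
gap_combinations <- function(gaps) {
  if (nrow(gaps) == 0L) return(list(integer(0)))
  grids <- lapply(seq_len(nrow(gaps)), function(i)
    seq.int(gaps$min_nt[i], gaps$max_nt[i]))
  out <- list(integer(0))
  for (g in grids) {
    out <- unlist(lapply(out, function(prefix)
      lapply(g, function(v) c(prefix, v))), recursive = FALSE)
  }
  out
}
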