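#' Parse a protein tag specification
#'
#' A tag is a short protein motif written as one-letter residue codes
#' with `X` marking wildcard positions, optionally separated by dashes,
#' underscores or whitespace: `"P-XXX-D-X-K-X-G"` is the inositol-binding
#' consensus of the inositol polyphosphate kinase superfamily, nine
#' positions of which four are fixed.
#'
#' Wildcard positions admit any standard residue by default; a
#' restricted `wildcard_allowed` set may be attached, in which case it
#' is enforced at the protein level by [filter_wildcards()] (a
#' residue-set restriction is deliberately not compiled into the
#' nucleotide pattern, where the union of codons would be a weaker
#' constraint than the residue-level rule).
#'
#' @param text Tag string, residues and `X` with optional separators.
#' @param name Label for the tag; defaults to the input text.
#' @param wildcard_allowed Optional character vector of residues allowed
#'   at wildcard positions (subset of [AMINO_ACIDS]).
#' @return A `tag_spec` object: a list with `name` and `positions`, one
#'   entry per residue with fields `kind` (`"fixed"` or `"wildcard"`),
#'   `residue` and `allowed`.
#' @examples
#' spec <- parse_tag("P-XXX-D-X-K-X-G")
#' tag_length(spec)          # 9
#' @export
parse_tag <- function(text, name = text, wildcard_allowed = NULL) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  clean <- gsub("[-_[:space:]]+", "", toupper(text))
  if (nchar(clean) == 0L) stop("empty tag specification")
  chars <- strsplit(clean, "", fixed = TRUE)[[1]]
  if (!is.null(wildcard_allowed)) {
    wildcard_allowed <- unique(toupper(wildcard_allowed))
    bad <- setdiff(wildcard_allowed, AMINO_ACIDS)
    if (length(bad) > 0L)
      stop("wildcard allowed set contains non-standard letters: ",
           paste(bad, collapse = ", "))
    if (length(wildcard_allowed) == 0L)
      stop("wildcard allowed set must be non-empty")
  }
  positions <- lapply(seq_along(chars), function(i) {
    ch <- chars[i]
    if (ch == "X") {
      list(kind = "wildcard", residue = NA_character_,
           allowed = wildcard_allowed %||% AMINO_ACIDS)
    } else if (ch %in% AMINO_ACIDS) {
      list(kind = "fixed", residue = ch, allowed = ch)
    } else {
      stop(sprintf("cannot parse tag: unknown letter '%s' at position %d",
                   ch, i))
    }
  })
  if (!any(vapply(positions, function(p) p$kind == "fixed", logical(1))))
    stop("tag must contain at least one fixed residue position")
  structure(list(name = name, positions = positions), class = "tag_spec")
}

#' Number of residue positions in a tag
#' @param spec A `tag_spec`.
#' @return Integer.
#' @export
tag_length <- function(spec) {
  stopifnot(inherits(spec, "tag_spec"))
  length(spec$positions)
}

# indices (1-based) of fixed positions
fixed_positions <- function(spec) {
  which(vapply(spec$positions, function(p) p$kind == "fixed", logical(1)))
}

#' @export
print.tag_spec <- function(x, ...) {
  letters <- vapply(x$positions, function(p)
    if (p$kind == "fixed") p$residue else "X", character(1))
  cat("Protein tag:", paste(letters, collapse = "-"), "\n")
  cat(sprintf("  %d positions (%d fixed, %d wildcard)\n",
              length(letters), length(fixed_positions(x)),
              length(letters) - length(fixed_positions(x))))
  invisible(x)
}
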