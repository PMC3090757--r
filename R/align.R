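#' Read a substitution matrix in NCBI format
#'
#' Parses the plain-text scoring matrix format used by NCBI BLAST
#' (comment lines starting with `#`, a header row of residue letters,
#' then one labelled row per residue). The matrix must be symmetric.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with residue dimnames.
#' @export
read_substitution_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[1L]), "[[:space:]]+")[[1]]
  n <- length(header)
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  for (ln in lines[-1L]) {
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != n + 1L)
      stop("malformed matrix row: ", ln)
    m[parts[1L], ] <- as.numeric(parts[-1L])
  }
  if (anyNA(m)) stop("incomplete substitution matrix: ", path)
  if (!isSymmetric(unname(m))) stop("substitution matrix is not symmetric")
  m
}

# BLOSUM62 bundled in NCBI format, read once per session
blosum62_env <- new.env(parent = emptyenv())

#' The BLOSUM62 substitution matrix
#'
#' Loads the bundled BLOSUM62 matrix (NCBI format, including the
#' ambiguity codes B, Z, X and the stop `*`).
#'
#' @return Numeric matrix with residue dimnames.
#' @export
blosum62 <- function() {
  if (is.null(blosum62_env$m)) {
    blosum62_env$m <- read_substitution_matrix(
      system.file("extdata", "BLOSUM62.txt", package = "tagscan",
                  mustWork = TRUE))
  }
  blosum62_env$m
}

zero_alignment <- function() {
  structure(list(score = 0,
                 query_interval = c(NA_integer_, NA_integer_),
                 target_interval = c(NA_integer_, NA_integer_),
                 identity = NA_real_,
                 gap_count = 0L,
                 pairs = data.frame(q = integer(0), t = integer(0))),
            class = "alignment_result")
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment of two protein sequences under a
#' substitution matrix and affine gap penalties; a gap of length k
#' costs `gap_open + k * gap_extend` (BLAST convention; the defaults
#' 11/1 with BLOSUM62 are the BLAST protein defaults). Ties between
#' equal-scoring cells are broken towards the earliest
#' (query end, target end).
#'
#' @param query,target Amino-acid strings over the letters of `matrix`.
#' @param matrix Substitution matrix; default [blosum62()].
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Per-residue gap extension penalty (positive).
#' @return An `alignment_result`: `score` (0 for empty input or no
#'   positive-scoring alignment), `query_interval` / `target_interval`
#'   (1-based inclusive), `identity` (percent identical aligned
#'   columns), `gap_count` (gapped columns) and `pairs`, a data frame
#'   of aligned positions with `NA` at gaps.
#' @examples
#' smith_waterman("PLLVDSKLG", "PLLVDSKLG")$score
#' @export
smith_waterman <- function(query, target, matrix = blosum62(),
                           gap_open = 11, gap_extend = 1) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(target), length(target) == 1L,
            is.matrix(matrix), gap_open >= 0, gap_extend >= 0)
  if (nchar(query) == 0L || nchar(target) == 0L) return(zero_alignment())
  qc <- strsplit(toupper(query), "", fixed = TRUE)[[1]]
  tc <- strsplit(toupper(target), "", fixed = TRUE)[[1]]
  qi <- match(qc, rownames(matrix))
  ti <- match(tc, colnames(matrix))
  if (anyNA(qi))
    stop("query contains letters absent from the substitution matrix: ",
         paste(unique(qc[is.na(qi)]), collapse = ", "))
  if (anyNA(ti))
    stop("target contains letters absent from the substitution matrix: ",
         paste(unique(tc[is.na(ti)]), collapse = ", "))
  res <- sw_align_cpp(qi, ti, matrix, gap_open, gap_extend)
  if (res$score <= 0) return(zero_alignment())
  pairs <- data.frame(q = res$q, t = res$t)
  both <- !is.na(pairs$q) & !is.na(pairs$t)
  ident <- 100 * sum(qc[pairs$q[both]] == tc[pairs$t[both]]) / nrow(pairs)
  structure(list(score = res$score,
                 query_interval = range(pairs$q, na.rm = TRUE),
                 target_interval = range(pairs$t, na.rm = TRUE),
                 identity = ident,
                 gap_count = sum(!both),
                 pairs = pairs),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "Local alignment: score %.0f, query %d-%d vs target %d-%d, %.1f%% identity, %d gap columns\n",
    x$score, x$query_interval[1], x$query_interval[2],
    x$target_interval[1], x$target_interval[2],
    x$identity, x$gap_count))
  invisible(x)
}

#' Do the two tags align onto each other?
#'
#' Given a local alignment of a candidate protein against a reference,
#' reports whether at least one aligned column pairs a residue of the
#' candidate's tag with a residue of the reference's tag -- the
#' "correspondence between tags" criterion used to judge a candidate.
#'
#' @param result An `alignment_result` from [smith_waterman()].
#' @param query_tag_interval,reference_tag_interval 1-based inclusive
#'   residue intervals `c(start, end)` of the tag in each sequence.
#' @return Logical.
#' @export
tag_correspondence <- function(result, query_tag_interval,
                               reference_tag_interval) {
  stopifnot(inherits(result, "alignment_result"),
            length(query_tag_interval) == 2L,
            length(reference_tag_interval) == 2L)
  p <- result$pairs
  if (nrow(p) == 0L) return(FALSE)
  both <- !is.na(p$q) & !is.na(p$t)
  any(both &
        p$q >= query_tag_interval[1] & p$q <= query_tag_interval[2] &
        p$t >= reference_tag_interval[1] & p$t <= reference_tag_interval[2])
}
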