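#' Genetic code tables
#'
#' A thin wrapper around the NCBI translation tables shipped with
#' Biostrings. The default is the standard code (table 1), which is
#' also the code used by plant mitochondria.
#'
#' @param table_id NCBI translation table identifier, as a string or
#'   integer (e.g. `"1"` for the standard code).
#' @return An object of class `genetic_code` with elements `id`, `map`
#'   (named character vector of 64 codons to one-letter residues, `"*"`
#'   for stops) and `stops` (the stop codons).
#' @examples
#' code <- genetic_code()
#' code$map[["ATG"]]
#' @export
genetic_code <- function(table_id = "1") {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  map <- map[order(names(map))]
  stopifnot(length(map) == 64L)
  structure(list(id = as.character(table_id),
                 map = map,
                 stops = names(map)[map == "*"]),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$id, "(", length(x$stops), "stop codons:",
      paste(x$stops, collapse = ", "), ")\n")
  invisible(x)
}

# residue -> character vector of synonymous codons
codon_families <- function(code) {
  stopifnot(inherits(code, "genetic_code"))
  split(names(code$map), unname(code$map))
}

#' Translate a nucleotide string in a single frame
#'
#' Translates from the first position; a trailing partial codon is
#' dropped. Stop codons are rendered as `"*"`; codons containing
#' ambiguous or non-nucleotide letters as `"X"`.
#'
#' @param nt Nucleotide string (case-insensitive).
#' @param code A [genetic_code()].
#' @return Single amino-acid string.
#' @examples
#' translate_nt("ATGTAA")  # "M*"
#' @export
translate_nt <- function(nt, code = genetic_code()) {
  stopifnot(is.character(nt), length(nt) == 1L)
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  starts <- seq.int(1L, by = 3L, length.out = n)
  aa <- unname(code$map[substring(nt, starts, starts + 2L)])
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

# reverse complement preserving IUPAC codes
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
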