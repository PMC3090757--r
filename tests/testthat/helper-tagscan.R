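# shared fixtures and independent oracles, all built in code

ipk_spec <- function() parse_tag("P-XXX-D-X-K-X-G")
ipk_pattern <- function() reverse_translate(ipk_spec())

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste0(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

# reverse-translate a concrete peptide with fixed codon choices (first
# codon of each family), handy for deterministic plants
peptide_to_nt <- function(aa, code = genetic_code()) {
  fams <- split(names(code$map), unname(code$map))
  paste0(vapply(strsplit(aa, "", fixed = TRUE)[[1]],
                function(a) fams[[a]][1], character(1)), collapse = "")
}

# plant a nucleotide string inside a random background at a 0-based
# position, returning the sequence
plant_at <- function(background, insert, pos0) {
  paste0(substr(background, 1, pos0), insert,
         substr(background, pos0 + nchar(insert) + 1, nchar(background)))
}

hit_key <- function(h) {
  paste(h$sequence_id, h$start, h$end, h$strand, h$mismatch_count,
        h$skip_count, h$swapped, h$edited_positions, sep = ":")
}

expect_same_hits <- function(a, b) {
  expect_identical(as.data.frame(a), as.data.frame(b))
}

# quadratic affine-gap local-alignment DP, score only: the independent
# oracle for the Smith-Waterman implementation (gap of length k costs
# open + k * ext)
sw_score_dp <- function(query, target, m = blosum62(),
                        open = 11, ext = 1) {
  qc <- strsplit(query, "", fixed = TRUE)[[1]]
  tc <- strsplit(target, "", fixed = TRUE)[[1]]
  qi <- match(qc, rownames(m))
  ti <- match(tc, colnames(m))
  n <- length(qi); mm <- length(ti)
  if (n == 0L || mm == 0L) return(0)
  NEG <- -1e9
  H <- matrix(0, n + 1L, mm + 1L)
  E <- matrix(NEG, n + 1L, mm + 1L)
  F <- matrix(NEG, n + 1L, mm + 1L)
  best <- 0
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(mm + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - open - ext, E[i, j - 1L] - ext)
      F[i, j] <- max(H[i - 1L, j] - open - ext, F[i - 1L, j] - ext)
      h <- H[i - 1L, j - 1L] + m[qi[i - 1L], ti[j - 1L]]
      v <- max(0, h, E[i, j], F[i, j])
      H[i, j] <- v
      if (v > best) best <- v
    }
  }
  best
}

rc <- function(x) tagscan:::revcomp_chr(x)
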