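#' Specification of a synthetic test genome
#'
#' Describes a set of random background records with planted,
#' codon-randomized tag instances and optional simulated C-to-U
#' editing. Backgrounds are i.i.d. with a given GC fraction; each
#' plant reverse-translates its tag with a uniformly random synonymous
#' codon at every position. With `editing_rate > 0`, each `T` of the
#' planted coding (mRNA-like) sequence is independently written as `C`
#' in the genome with that probability, emulating a transcript whose
#' genomic template requires C-to-U editing.
#'
#' @param seed Integer seed controlling all randomness of the
#'   simulation.
#' @param n_records Number of FASTA records.
#' @param record_length Length of each record in nt.
#' @param gc_fraction Background GC content in `[0, 1]`; default 0.5.
#' @param plants List of plants. Each is a list with fields `tag` (tag
#'   string or `tag_spec`), `position` (0-based start within the
#'   record), and optionally `record` (index, default 1), `strand`
#'   (`"+"`/`"-"`, default `"+"`) and `wildcards` (character vector of
#'   residues for the wildcard positions, or `"random"` to draw each
#'   uniformly from the position's allowed set).
#' @param editing_rate Probability that a genomic C is written where
#'   the planted coding sequence has T.
#' @return A `simulation_spec` object.
#' @export
simulation_spec <- function(seed = 1L, n_records = 1L,
                            record_length = 50000L, gc_fraction = 0.5,
                            plants = list(), editing_rate = 0) {
  stopifnot(n_records >= 0L, record_length >= 0L,
            gc_fraction >= 0, gc_fraction <= 1,
            editing_rate >= 0, editing_rate <= 1)
  plants <- lapply(plants, function(p) {
    stopifnot(!is.null(p$tag), !is.null(p$position))
    p$record <- as.integer(p$record %||% 1L)
    p$strand <- p$strand %||% "+"
    stopifnot(p$strand %in% c("+", "-"))
    p$wildcards <- p$wildcards %||% "random"
    if (!inherits(p$tag, "tag_spec")) p$tag <- parse_tag(p$tag)
    p$position <- as.integer(p$position)
    stopifnot(p$position >= 0L)
    if (p$record < 1L || p$record > n_records)
      stop("plant record index outside 1..n_records")
    if (p$position + 3L * tag_length(p$tag) > record_length)
      stop("plant does not fit in record")
    p
  })
  # planted intervals must not overlap within a record
  if (length(plants) > 1L) {
    iv <- data.frame(
      rec = vapply(plants, function(p) p$record, integer(1)),
      s = vapply(plants, function(p) p$position, integer(1)),
      e = vapply(plants, function(p)
        p$position + 3L * tag_length(p$tag), integer(1)))
    iv <- iv[order(iv$rec, iv$s), ]
    same <- iv$rec[-1L] == iv$rec[-nrow(iv)]
    if (any(same & iv$s[-1L] < iv$e[-nrow(iv)]))
      stop("planted positions overlap within a record")
  }
  structure(list(seed = as.integer(seed), n_records = as.integer(n_records),
                 record_length = as.integer(record_length),
                 gc_fraction = gc_fraction, plants = plants,
                 editing_rate = editing_rate),
            class = "simulation_spec")
}

empty_truth <- function() {
  data.frame(sequence_id = character(0), start = integer(0),
             end = integer(0), strand = character(0),
             tag_aa = character(0), mrna_nt = character(0),
             genome_nt = character(0), edited_offsets = character(0),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted tags
#'
#' Draws the background, reverse-translates and inserts each plant and
#' applies the editing corruption, all under the spec's seed, and
#' returns the sequences together with a truth table of planted hits
#' in the same 0-based half-open coordinates used by
#' [scan_sequence()]. Identical specs produce identical output.
#'
#' @param spec A [simulation_spec()].
#' @param code A [genetic_code()].
#' @return A list with `sequences` (named character vector), `truth`
#'   (data frame: `sequence_id`, `start`, `end`, `strand`, `tag_aa`,
#'   `mrna_nt` (the planted coding sequence), `genome_nt` (as written,
#'   strand-oriented), `edited_offsets` (comma-separated 0-based
#'   offsets rewritten by editing)) and the `spec`.
#' @export
simulate_genome <- function(spec, code = genetic_code()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  fams <- codon_families(code)
  gc <- spec$gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ids <- sprintf("record_%d", seq_len(spec$n_records))
  seqs <- character(spec$n_records)
  truth_rows <- list()
  for (r in seq_len(spec$n_records)) {
    chars <- if (spec$record_length > 0L)
      sample(names(probs), spec$record_length, replace = TRUE, prob = probs)
    else character(0)
    for (p in spec$plants) {
      if (p$record != r) next
      tag <- p$tag
      wc_idx <- which(vapply(tag$positions, function(q)
        q$kind == "wildcard", logical(1)))
      if (identical(p$wildcards, "random")) {
        wc <- vapply(wc_idx, function(i)
          sample(tag$positions[[i]]$allowed, 1L), character(1))
      } else {
        stopifnot(length(p$wildcards) == length(wc_idx))
        wc <- toupper(p$wildcards)
      }
      aa <- vapply(seq_along(tag$positions), function(i) {
        q <- tag$positions[[i]]
        if (q$kind == "fixed") q$residue else wc[match(i, wc_idx)]
      }, character(1))
      codons <- vapply(aa, function(a) {
        fam <- fams[[a]]
        fam[sample.int(length(fam), 1L)]
      }, character(1))
      mrna <- paste0(codons, collapse = "")
      g <- strsplit(mrna, "", fixed = TRUE)[[1]]
      ed <- integer(0)
      if (spec$editing_rate > 0) {
        tpos <- which(g == "T")
        ed <- tpos[runif(length(tpos)) < spec$editing_rate]
        g[ed] <- "C"
      }
      oriented <- if (p$strand == "-")
        strsplit(revcomp_chr(paste0(g, collapse = "")), "",
                 fixed = TRUE)[[1]]
      else g
      chars[(p$position + 1L):(p$position + length(g))] <- oriented
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        sequence_id = ids[r],
        start = p$position,
        end = p$position + length(g),
        strand = p$strand,
        tag_aa = paste0(aa, collapse = ""),
        mrna_nt = mrna,
        genome_nt = paste0(g, collapse = ""),
        edited_offsets = paste(ed - 1L, collapse = ","),
        stringsAsFactors = FALSE)
    }
    seqs[r] <- paste0(chars, collapse = "")
  }
  truth <- if (length(truth_rows) == 0L) empty_truth()
           else do.call(rbind, truth_rows)
  list(sequences = setNames(seqs, ids), truth = truth, spec = spec)
}

#' Write a simulated genome to FASTA (+ truth TSV)
#'
#' @param sim Result of [simulate_genome()].
#' @param fasta_path Output FASTA path.
#' @param truth_path Optional output TSV path for the truth table.
#' @return `fasta_path`, invisibly.
#' @export
write_simulation <- function(sim, fasta_path, truth_path = NULL) {
  write_fasta(sim$sequences, fasta_path)
  if (!is.null(truth_path))
    write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(fasta_path)
}

#' Plain random background sequence
#'
#' A single i.i.d. record with no plants, for false-positive
#' calibration against [expected_hit_count()].
#'
#' @param seed Integer seed.
#' @param length Sequence length in nt.
#' @param gc_fraction GC content; default 0.5 (uniform).
#' @return A nucleotide string.
#' @export
simulate_background_only <- function(seed, length, gc_fraction = 0.5) {
  stopifnot(length >= 0L)
  set.seed(seed)
  if (length == 0L) return("")
  gc <- gc_fraction
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(names(probs), length, replace = TRUE, prob = probs),
         collapse = "")
}
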