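test_that("a reverse-translated tag instance is found exactly once", {
  # one concrete codon choice per residue of PVGTDRKGG
  s <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  h <- scan_sequence(s, ipk_pattern(), scan_config())
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "+")
  expect_equal(h$start, 0L)
  expect_equal(h$end, 27L)
  expect_equal(h$box_starts, "0,12,18,24")
  expect_equal(h$mismatch_count, 0L)
  expect_equal(h$matched_nt, s)
  expect_same_hits(h, brute_force_scan(s, ipk_pattern(), scan_config()))
})

test_that("degenerate and empty inputs behave", {
  pat <- ipk_pattern()
  expect_equal(nrow(scan_sequence("", pat, scan_config())), 0L)
  expect_equal(nrow(scan_sequence("ACGT", pat, scan_config())), 0L)
  expect_equal(nrow(scan_sequence(strrep("N", 200), pat, scan_config())), 0L)
  expect_error(scan_sequence("ACGT", pat,
                             scan_config(max_mismatches = 13)),
               "mismatch budget")
})

test_that("minus-strand hits map back to forward coordinates", {
  s <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  h <- scan_sequence(rc(s), ipk_pattern(), scan_config())
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(c(h$start, h$end), c(0L, 27L))
  expect_equal(h$matched_nt, s)  # strand-oriented
  # with padding the coordinates reflect
  set.seed(5)
  bg <- random_dna(500)
  fwd <- plant_at(bg, s, 100)
  rev <- rc(fwd)
  hf <- scan_sequence(fwd, ipk_pattern(), scan_config())
  hr <- scan_sequence(rev, ipk_pattern(), scan_config())
  expect_equal(nrow(hf), nrow(hr))
  expect_setequal(paste(500 - hf$end, 500 - hf$start,
                        ifelse(hf$strand == "+", "-", "+")),
                  paste(hr$start, hr$end, hr$strand))
})

test_that("overlapping placements are all reported", {
  pat <- reverse_translate(parse_tag("M"))
  h <- scan_sequence("ATGATG", pat, scan_config(strands = "plus"))
  expect_equal(h$start, c(0L, 3L))
  expect_equal(h$end, c(3L, 6L))
})

test_that("mismatch budgets admit corrupted instances monotonically", {
  s0 <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  s1 <- sub("GAT", "GGT", s0)  # corrupt the anchored A of the D box
  expect_equal(nrow(scan_sequence(s1, ipk_pattern(), scan_config())), 0L)
  h1 <- scan_sequence(s1, ipk_pattern(), scan_config(max_mismatches = 1))
  expect_equal(nrow(h1), 1L)
  expect_equal(h1$mismatch_count, 1L)
  # monotonicity over random sequences
  set.seed(7)
  for (i in 1:8) {
    s <- random_dna(2000)
    prev <- character(0)
    for (mm in 0:2) {
      h <- scan_sequence(s, ipk_pattern(), scan_config(max_mismatches = mm))
      cur <- paste(h$start, h$end, h$strand)
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("N and soft-masked bases follow the matching rules", {
  pat <- reverse_translate(parse_tag("M"))   # ATG, all anchored
  expect_equal(nrow(scan_sequence("ANG", pat, scan_config(strands = "plus"))),
               0L)
  expect_equal(nrow(scan_sequence("ANG", pat,
                                  scan_config(strands = "plus",
                                              ambiguous_base_matches = TRUE))),
               1L)
  # R = A/G matches the A of ATG under ambiguity, not strictly
  expect_equal(nrow(scan_sequence("RTG", pat, scan_config(strands = "plus"))),
               0L)
  expect_equal(nrow(scan_sequence("RTG", pat,
                                  scan_config(strands = "plus",
                                              ambiguous_base_matches = TRUE))),
               1L)
  # N inside a gap is unconstrained
  ipk <- ipk_pattern()
  s <- "CCANNNNNNNNNGATNNNAAANNNGGT"
  expect_equal(nrow(scan_sequence(s, ipk, scan_config(strands = "plus"))), 1L)
  # soft-masked bases fold to uppercase by default, can be excluded
  expect_equal(nrow(scan_sequence("atg", pat, scan_config(strands = "plus"))),
               1L)
  expect_equal(nrow(scan_sequence("atg", pat,
                                  scan_config(strands = "plus",
                                              include_softmasked = FALSE))),
               0L)
})

test_that("skips tolerate one deletion per box and are counted apart", {
  s0 <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  s_del <- paste0(substr(s0, 1, 13), substr(s0, 15, 27))  # delete one D-box nt
  strict <- scan_sequence(s_del, ipk_pattern(), scan_config())
  expect_equal(nrow(strict), 0L)
  skipped <- scan_sequence(s_del, ipk_pattern(), scan_config(allow_skips = TRUE))
  expect_true(nrow(skipped) >= 1L)
  expect_true(all(skipped$skip_count >= 1L))
  expect_true(all(skipped$mismatch_count == 0L))
  # the one-deletion reading of the planted corruption is among the hits
  expect_true(any(skipped$start == 0L & skipped$end == 26L &
                    skipped$skip_count == 1L))
  expect_same_hits(skipped,
                   brute_force_scan(s_del, ipk_pattern(),
                                    scan_config(allow_skips = TRUE)))
})

test_that("adjacent box swaps are found and flagged", {
  # exchange the D and K boxes of a concrete instance
  s_sw <- "CCAGTTGGAACTAAACGTGATGGCGGT"
  cfg <- scan_config(allow_swaps = TRUE)
  expect_equal(nrow(scan_sequence(s_sw, ipk_pattern(), scan_config())), 0L)
  h <- scan_sequence(s_sw, ipk_pattern(), cfg)
  expect_equal(nrow(h), 1L)
  expect_true(h$swapped)
  expect_same_hits(h, brute_force_scan(s_sw, ipk_pattern(), cfg))
})

test_that("scanner agrees with the exhaustive oracle on random inputs", {
  set.seed(123)
  pat <- ipk_pattern()
  tag_nt <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  configs <- list(scan_config(),
                  scan_config(max_mismatches = 1),
                  scan_config(max_mismatches = 2),
                  scan_config(editing = editing_policy(forward_CtoU = TRUE)),
                  scan_config(allow_skips = TRUE),
                  scan_config(allow_swaps = TRUE))
  for (i in 1:12) {
    s <- random_dna(2000)
    if (i %% 2 == 0) s <- plant_at(s, tag_nt, 400 + i * 50)
    cfg <- configs[[(i %% length(configs)) + 1L]]
    expect_same_hits(scan_sequence(s, pat, cfg),
                     brute_force_scan(s, pat, cfg))
  }
})

test_that("oracle agreement holds for a variable-gap pattern", {
  # hand-built pattern with an elastic gap: ATG -[0..3]- TGG
  pat <- reverse_translate(parse_tag("M-W"))
  pat$gaps$min_nt <- 0L
  pat$gaps$max_nt <- 3L
  set.seed(9)
  for (i in 1:6) {
    s <- random_dna(300)
    s <- plant_at(s, "ATGCTTGG", 50)   # gap of 2
    expect_same_hits(scan_sequence(s, pat, scan_config()),
                     brute_force_scan(s, pat, scan_config()))
  }
  h <- scan_sequence("ATGCTTGG", pat, scan_config(strands = "plus"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$end - h$start, 8L)
})

test_that("scanning is deterministic", {
  set.seed(33)
  s <- plant_at(random_dna(3000), "CCAGTTGGAACTGATCGTAAAGGCGGT", 1000)
  cfg <- scan_config(max_mismatches = 1)
  expect_identical(scan_sequence(s, ipk_pattern(), cfg),
                   scan_sequence(s, ipk_pattern(), cfg))
})

test_that("expected hit counts multiply per-position set frequencies", {
  expect_equal(match_probability(ipk_pattern()), 2^-18)
  full <- reverse_translate(parse_tag("G"))  # GG{ACGT}: prob 1/16
  expect_equal(match_probability(full), 1 / 16)
  # a fully degenerate single box would have probability 1 per placement
  pat1 <- reverse_translate(parse_tag("M"))
  pat1$boxes[[1]]$sets <- rep(list(c("A", "C", "G", "T")), 3)
  expect_equal(match_probability(pat1), 1)
  L <- 10000
  expect_equal(expected_hit_count(ipk_pattern(), L, scan_config()),
               2 * (L - 27 + 1) * 2^-18)
  expect_equal(expected_hit_count(ipk_pattern(), L,
                                  scan_config(strands = "plus")),
               (L - 27 + 1) * 2^-18)
  expect_error(expected_hit_count(ipk_pattern(), L,
                                  scan_config(max_mismatches = 1)),
               "strict")
})

test_that("FASTA scanning concatenates per-record hits in file order", {
  tag_nt <- "CCAGTTGGAACTGATCGTAAAGGCGGT"
  set.seed(77)
  seqs <- c(chrA = plant_at(random_dna(900), tag_nt, 120),
            chrB = plant_at(random_dna(900), tag_nt, 600))
  fa <- tempfile(fileext = ".fa")
  tagscan:::write_fasta(seqs, fa)
  h <- scan_fasta(fa, ipk_pattern(), scan_config())
  expect_equal(h$sequence_id, c("chrA", "chrB"))
  expect_equal(h$start, c(120L, 600L))
  # gzip transparency
  gz <- tempfile(fileext = ".fa.gz")
  con <- gzfile(gz, "wt")
  writeLines(readLines(fa), con)
  close(con)
  expect_identical(as.data.frame(scan_fasta(gz, ipk_pattern(), scan_config())),
                   as.data.frame(h))
  # all-N file
  fn <- tempfile(fileext = ".fa")
  writeLines(c(">n1", strrep("N", 300)), fn)
  expect_equal(nrow(scan_fasta(fn, ipk_pattern(), scan_config())), 0L)
})
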