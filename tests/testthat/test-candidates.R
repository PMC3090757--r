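tag_nt <- "CCAGTTGGAACTGATCGTAAAGGCGGT"  # PVGTDRKGG

central_fixture <- function(len = 10000, pos = 5000, seed = 21) {
  set.seed(seed)
  s <- plant_at(random_dna(len), tag_nt, pos)
  h <- scan_sequence(s, ipk_pattern(), scan_config())
  list(seq = s, hit = h[h$start == pos, ])
}

test_that("candidate windows default to 1200 nt with codon-aligned flanks", {
  fx <- central_fixture()
  cand <- extract_candidate(fx$seq, fx$hit)
  expect_equal(nchar(cand$window_nt), 1200L)
  expect_false(cand$truncated_left)
  expect_false(cand$truncated_right)
  expect_equal(cand$flank_left_nt %% 3L, 0L)
  expect_equal(cand$flank_right_nt %% 3L, 0L)
  expect_equal(cand$flank_left_nt + 27L + cand$flank_right_nt, 1200L)
  expect_equal(cand$window_start, fx$hit$start - cand$flank_left_nt)
  expect_equal(cand$window_end, fx$hit$end + cand$flank_right_nt)
})

test_that("windows clamp at sequence ends with truncation flags", {
  set.seed(22)
  s <- plant_at(random_dna(2000), tag_nt, 10)
  h <- scan_sequence(s, ipk_pattern(), scan_config())
  h <- h[h$start == 10, ]
  cand <- extract_candidate(s, h)
  expect_true(cand$truncated_left)
  expect_false(cand$truncated_right)
  expect_equal(cand$flank_left_nt, 9L)   # 10 nt available, codon-rounded
  expect_lt(nchar(cand$window_nt), 1200L)
  expect_error(extract_candidate(s, list(start = -5, end = 22, strand = "+")),
               "outside")
  expect_error(extract_candidate("ACGT", list(start = 0, end = 27,
                                              strand = "+")),
               "outside")
})

test_that("minus-strand extraction mirrors the plus-strand window", {
  set.seed(23)
  fwd <- plant_at(random_dna(5000), tag_nt, 2500)
  rev <- rc(fwd)
  hf <- scan_sequence(fwd, ipk_pattern(), scan_config())
  hf <- hf[hf$start == 2500 & hf$strand == "+", ]
  hr <- scan_sequence(rev, ipk_pattern(), scan_config())
  hr <- hr[hr$strand == "-" & hr$start == 5000 - 2527, ]
  expect_equal(nrow(hr), 1L)
  cf <- extract_candidate(fwd, hf)
  cr <- extract_candidate(rev, hr)
  expect_equal(cr$window_nt, cf$window_nt)
  expect_equal(cr$truncated_left, cf$truncated_left)
  # forward coordinates of the minus window are the reflection
  expect_equal(cr$window_start, 5000 - cf$window_end)
  expect_equal(cr$window_end, 5000 - cf$window_start)
})

test_that("translation is anchored at the tag's first codon", {
  h <- scan_sequence(tag_nt, ipk_pattern(), scan_config())
  cand <- translate_window(extract_candidate(tag_nt, h[1, ], window_nt = 27))
  expect_equal(cand$protein, "PVGTDRKGG")
  expect_equal(cand$tag_aa, "PVGTDRKGG")
  expect_equal(cand$tag_offset_aa, 0L)

  # stop rendering in a single-box fixture
  mpat <- reverse_translate(parse_tag("M"))
  hm <- scan_sequence("ATGTAA", mpat, scan_config(strands = "plus"))
  cm <- translate_window(extract_candidate("ATGTAA", hm[1, ], window_nt = 6))
  expect_equal(cm$protein, "M*")

  # 600-nt random-codon flanks put the tag at amino-acid offset 200
  set.seed(24)
  flank <- function() paste0(replicate(200,
    sample(setdiff(names(genetic_code()$map),
                   genetic_code()$stops), 1)), collapse = "")
  s <- paste0(flank(), tag_nt, flank())
  h <- scan_sequence(s, ipk_pattern(), scan_config(strands = "plus"))
  h <- h[h$start == 600, ]
  cand <- translate_window(extract_candidate(s, h, window_nt = 1227))
  expect_equal(cand$tag_offset_aa, 200L)
  expect_equal(cand$tag_aa, "PVGTDRKGG")
  expect_equal(substr(cand$protein, 201, 209), "PVGTDRKGG")
})

test_that("the wildcard composition rule passes and rejects as printed", {
  spec <- ipk_spec()
  expect_true(filter_wildcards("PLLVDSKLG", spec)$pass)
  v <- filter_wildcards("PVGTDRKGG", spec)
  expect_false(v$pass)
  expect_match(v$reasons, "position 6")
  expect_true(filter_wildcards("PAAADAKAG", spec)$pass)
  # fixed-position deviation is reported, not silently dropped
  v2 <- filter_wildcards("ALLVDSKLG", spec)
  expect_false(v2$pass)
  expect_match(v2$reasons[1], "fixed residue 'P'")
  # length mismatch (e.g. after a skip) fails with a reason
  v3 <- filter_wildcards("PLLVDSKL", spec)
  expect_false(v3$pass)
  # a restricted wildcard set on the tag overrides the default set
  spec2 <- parse_tag("P-X-G", wildcard_allowed = c("A"))
  expect_true(filter_wildcards("PAG", spec2)$pass)
  expect_false(filter_wildcards("PLG", spec2)$pass)
})

test_that("stop-free span is the run containing the tag", {
  # stop, 100 residues, 9-residue tag, 89 residues, stop -> span 198
  set.seed(25)
  safe <- setdiff(names(genetic_code()$map), genetic_code()$stops)
  codons <- function(n) paste0(sample(safe, n, replace = TRUE), collapse = "")
  s <- paste0("TAA", codons(100), tag_nt, codons(89), "TGA", codons(20))
  h <- scan_sequence(s, ipk_pattern(), scan_config(strands = "plus"))
  h <- h[h$start == 303, ]
  cand <- translate_window(extract_candidate(s, h, window_nt = nchar(s)))
  sf <- stop_free_span(cand)
  expect_false(sf$tag_contains_stop)
  expect_equal(sf$span_aa, 198L)
  expect_equal(sf$bounds, c(2L, 199L))

  # no stops anywhere: the whole protein
  s2 <- paste0(codons(50), tag_nt, codons(41))
  h2 <- scan_sequence(s2, ipk_pattern(), scan_config(strands = "plus"))
  cand2 <- translate_window(extract_candidate(s2, h2[1, ], window_nt = 600))
  expect_equal(stop_free_span(cand2)$span_aa, 100L)

  # a stop inside the tag region flags the candidate
  cand3 <- cand2
  cand3$protein <- paste0(substr(cand2$protein, 1, 52), "*",
                          substr(cand2$protein, 54, nchar(cand2$protein)))
  sf3 <- stop_free_span(cand3)
  expect_true(sf3$tag_contains_stop)
  expect_true(is.na(sf3$span_aa))
})

test_that("subregions stay centred on the tag and clamp at the ends", {
  fx <- central_fixture()
  cand <- translate_window(extract_candidate(fx$seq, fx$hit))
  sub50 <- subregion(cand, 50)
  expect_equal(nchar(sub50$protein), 50L)
  expect_equal(substr(sub50$protein, sub50$tag_offset_aa + 1,
                      sub50$tag_offset_aa + 9), cand$tag_aa)
  # offsets map back into the full protein
  expect_equal(substr(cand$protein, sub50$offset_in_protein_aa + 1,
                      sub50$offset_in_protein_aa + 50), sub50$protein)
  big <- subregion(cand, 10000)
  expect_equal(big$protein, cand$protein)
  # near an end, missing residues are taken from the other side
  short <- translate_window(extract_candidate(tag_nt, scan_sequence(
    tag_nt, ipk_pattern(), scan_config())[1, ], window_nt = 27))
  expect_equal(subregion(short, 50)$protein, "PVGTDRKGG")
})

test_that("zero-mismatch hits round-trip through extraction and translation", {
  spec <- ipk_spec()
  pat <- ipk_pattern()
  tag_regex <- "^P...D.K.G$"
  set.seed(26)
  for (i in 1:10) {
    sim <- simulate_genome(simulation_spec(
      seed = 1000 + i, n_records = 1, record_length = 6000,
      plants = list(list(tag = spec, position = 1200 + 300 * i,
                         strand = sample(c("+", "-"), 1)))))
    s <- sim$sequences[[1]]
    tr <- sim$truth
    h <- scan_sequence(s, pat, scan_config(), sequence_id = "record_1")
    found <- h[h$start == tr$start & h$strand == tr$strand, ]
    expect_equal(nrow(found), 1L)
    cand <- translate_window(extract_candidate(s, found))
    expect_equal(cand$tag_aa, tr$tag_aa)
    expect_match(cand$tag_aa, tag_regex)
    expect_equal(cand$flank_left_nt %% 3L, 0L)
    expect_equal(cand$flank_right_nt %% 3L, 0L)
  }
})

test_that("plants drawn from the allowed set always pass the filter", {
  spec_allowed <- parse_tag("P-XXX-D-X-K-X-G",
                            wildcard_allowed = FILTER_ALLOWED)
  pat <- ipk_pattern()
  for (i in 1:10) {
    sim <- simulate_genome(simulation_spec(
      seed = 2000 + i, n_records = 1, record_length = 4000,
      plants = list(list(tag = spec_allowed, position = 1800))))
    s <- sim$sequences[[1]]
    h <- scan_sequence(s, pat, scan_config())
    found <- h[h$start == 1800 & h$strand == "+", ]
    expect_equal(nrow(found), 1L)
    cand <- translate_window(extract_candidate(s, found))
    expect_true(filter_wildcards(cand, ipk_spec())$pass)
  }
})
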