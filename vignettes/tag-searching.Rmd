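---
title: "Searching genomes for protein tags: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searching genomes for protein tags: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagscan)
```

## The problem

Homology search fails when a gene family is so heterogeneous that no
full-length alignment reaches significance, and it fails doubly in
plant organelles, where C-to-U RNA editing makes the genomic DNA
differ from the mRNA it encodes. The inositol polyphosphate kinase
(IPK) superfamily — IP6 kinases, inositol polyphosphate multikinases
and IP3 3-kinases — is a case in point: its members share almost
nothing at the sequence level except a nine-residue inositol-binding
consensus, `P-XXX-D-X-K-X-G`, in which only four residues are fixed.
No IP6 kinase has been found in plant genomes by similarity methods,
yet its product (the pyrophosphate IP7) and its enzymatic activity are
both demonstrable in plants.

`tagscan` implements the alternative: treat the short diagnostic motif
("tag") as the search key. The tag is reverse-translated into a
degenerate nucleotide pattern, the genome is scanned directly at the
DNA level on both strands — optionally tolerating C-to-U editing — and
every match is expanded into a candidate gene region that is
translated, screened and ranked.

## From tag to nucleotide pattern

A tag is an ordered list of positions, each either *fixed* to one
residue or a *wildcard* (`X`). `reverse_translate()` compiles it under
a genetic code (default: the standard table, which plant mitochondria
also use; selectable for other organelles):

* each fixed residue becomes a 3-nt **box** whose per-position
  nucleotide sets are the union of the residue's synonymous codons;
  positions admitting a single nucleotide are flagged **anchored**;
* each maximal run of `k` wildcards becomes a fixed **gap** of `3k` nt,
  so the reading frame is preserved across the whole pattern.

```{r}
pat <- reverse_translate(parse_tag("P-XXX-D-X-K-X-G"))
format(pat)
```

The span is `3 × 9 = 27` nt and the per-placement match probability on
uniform background is $(1/16)(1/32)(1/32)(1/16) = 2^{-18}$
(`match_probability()`), i.e. about 8 expected placements per megabase
scanned on both strands — the false-positive load the post-processing
filters are sized for.

Two compilation choices deserve justification:

* **Restricted wildcards are not compiled into DNA.** A wildcard may
  carry a restricted residue set (the screening rule below), but the
  union of those residues' codons is a strictly weaker constraint at
  the DNA level than the residue rule is at the protein level. The
  restriction is therefore enforced after translation
  (`filter_wildcards()`), and wildcards always compile to unconstrained
  gaps.
* **Six-codon residues over-match by construction.** For residues
  whose codon family is not a Cartesian product of its position sets
  (L, S, R in the standard code), the compiled box admits a few codons
  of a sister residue (e.g. the L box admits `TTT` = F). This is
  inherent to per-position degeneracy; the protein-level fixed-residue
  check catches the strays, and such candidates are reported as failed
  with reasons rather than silently dropped.

## Editing-aware matching

In plant mitochondria the dominant editing event rewrites a genomic C
to U in the transcript. A gene stored in "pre-editing" form therefore
shows `C` where the functional mRNA — and hence the tag pattern —
expects `T`. `editing_policy(forward_CtoU = TRUE)` widens every
T-admitting pattern position to also admit C; the converse relaxation
(`reverse_UtoC`) is available separately. The expansion is monotone
(hits of the strict pattern are always a subset), and the scanner
reports, per hit, exactly which positions relied on it
(`edited_positions`).

Note that the inositol-binding pattern itself is a *fixpoint* of the
forward expansion — every T-containing set already contains C — so
editing tolerance is free for this tag. Tags containing residues with
anchored T positions (F, M, W, Y, I, ...) are genuinely
editing-sensitive, which is how the simulator exercises the rescue
path.

## Scanning

`scan_sequence()` enumerates every placement satisfying the pattern:
all gap lengths within each gap interval, both strands (minus-strand
hits are found on the reverse complement and mapped back to forward
coordinates), with a configurable mismatch budget over box positions.
Coordinates are 0-based half-open internally and converted to 1-based
inclusive in all user-facing output (TSV/GFF3).

Semantics are *defined* by `brute_force_scan()`, a deliberately naive
per-start walker, and the equivalence of the two implementations on
random sequences is a standing property of the test suite. Further
matching rules:

* `N` (or any IUPAC ambiguity code) never matches a constrained
  position under strict matching; with `ambiguous_base_matches = TRUE`
  a code matches when its base set intersects the allowed set. Gap
  positions are unconstrained either way.
* Soft-masked lowercase is matched case-folded by default;
  `include_softmasked = FALSE` excludes it from constrained positions.
* **Skips** (`allow_skips`): at most one single-nucleotide deletion
  per box, counted separately from mismatches. The historical
  structured-motif tools admit "skips" without a published budget; one
  per box is the minimal useful reading and keeps enumeration bounded.
* **Swaps** (`allow_swaps`): one exchange of two adjacent boxes,
  flagged in the hit. Off by default, as a swap destroys the reading
  frame.
* Overlapping and nested hits are all reported; exact duplicates (same
  start, end, strand) are reported once, keeping the variant with the
  fewest mismatches, then fewest skips.

## Candidate regions

`extract_candidate()` cuts a window of `window_nt` nucleotides (default
1200, i.e. about 400 codons — the customary extraction width around
this tag) centred on the hit. The flanks are rounded *down* to codon
multiples — left flank `3⌊(w − s)/6⌋`, remainder to the right — so the
single-frame translation is anchored at the tag's first box; windows
are clamped at sequence ends with explicit truncation flags, and
minus-strand hits yield the reverse-complement (coding) window. The
exact symmetry and rounding convention is this package's own choice;
only "about 1200 nt" is canonical.

`translate_window()` renders stops as `*` and codons containing
non-ACGT letters as `X`. Screening then has three independent parts:

* `filter_wildcards()`: fixed positions must carry exactly their
  residue; wildcard positions must come from the allowed set, default
  `{L,V,T,M,I,A,S,G,C}` — residues small and apolar enough for the
  inositol-binding pocket. Failures carry per-position reasons.
* `stop_free_span()`: the length of the longest stop-free run of the
  translated window containing the whole tag, an open-reading-frame
  plausibility score. The run containing the tag is unique; a stop
  inside the tag region flags the candidate instead.
* `subregion()`: clamped, tag-centred protein substrings (e.g. 50 or
  410 residues) for cross-organism comparison, with offset bookkeeping
  that maps back to the full translation.

## Ranking against references

`smith_waterman()` is a full affine-gap local aligner (Rcpp core, exact
integer arithmetic in doubles) with the BLAST protein defaults:
BLOSUM62, gap open 11, gap extend 1, a gap of length $k$ costing
$11 + k$. Ties are broken towards the earliest (query end, target
end). The bundled BLOSUM62 is the canonical NCBI matrix, and the test
suite checks both a pure-R quadratic DP oracle and an established
aligner against it. `tag_correspondence()` reports whether any aligned
column pairs candidate-tag and reference-tag residues — the criterion
that distinguishes "aligns somewhere" from "aligns at the
inositol-binding site". Multiple alignment and tree building are out
of scope; ranking is pairwise only.

## The synthetic genome generator

All validation data are generated in code (`simulate_genome()`):
i.i.d. backgrounds with adjustable GC, planted tag instances with
uniformly random synonymous codon choice and per-position wildcard
draws, optional strand flips, and editing corruption — each planted
`T` rewritten to `C` with probability `editing_rate`, recorded in the
truth table. Defaults (one 50-kb record, GC 0.5, editing off) are
sized so that a planted tag dominates the ~`2^-18` background rate by
orders of magnitude.

What the simulator deliberately does **not** model: higher-order
sequence composition (real genomes are not i.i.d.), intron structure,
and trans-splicing fragmentation of genes. Passing recall tests
therefore demonstrates correctness of the matcher and of the
coordinate bookkeeping, not sensitivity on real organellar genomes;
conversely the background calibration (`expected_hit_count()`, Poisson
4σ check) is exact for the i.i.d. model it assumes.

## Validation sizes and numerical choices

The test suite runs, among others: scanner-vs-oracle equivalence on
1,000 random 2-kb sequences across mismatch budgets 0–2 on both
strands; 100 seeded planted-recovery simulations (5-kb records,
including total-editing rescue scenarios on an editing-sensitive tag);
a 1-Mb uniform background calibrated against the analytic expectation;
and 500 random protein pairs (≤ 200 aa) against a quadratic DP
alignment oracle. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

Remaining conventions, chosen once: hits sort by (start, strand, end);
gap-length combinations enumerate lexicographically; the dash count in
the customary printed form of the pattern is typographically ambiguous,
and gaps are fixed at 3 nt per wildcard (9/3/3 for the inositol tag),
which is the only frame-preserving reading; `expected_hit_count()`
requires a strict configuration because the mismatch-tolerant
expectation depends on the budget's distribution over positions.

## Limitations

* Scanning is linear per pattern (no index structures); a 1-Mb record
  scans in seconds, whole plant chromosomes in minutes.
* The skip/swap budgets are this package's documented reading of
  loosely specified historical semantics, not a reconstruction.
* Secondary motifs of the family (ATP-binding site, C-terminal motif,
  "SSLL") have no published sequence definitions usable here; they can
  be supplied as additional tags via `parse_tag()` but are not built
  in.
* No E-value statistics for alignment scores; ranking is by raw score.
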