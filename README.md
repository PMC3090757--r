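# tagscan

Gene identification in genomes by **protein tag searching**.

Some gene families are too heterogeneous for similarity search: their
members share almost nothing except a short diagnostic motif. The
inositol polyphosphate kinase (IPK) superfamily is the motivating
case — IP6 kinases, multikinases and IP3 3-kinases share only the
nine-residue inositol-binding consensus

```
P-XXX-D-X-K-X-G
```

(four fixed residues, five wildcards). `tagscan` searches nucleotide
sequence directly for such tags: it compiles the protein motif into a
degenerate DNA pattern by reverse translation, scans both strands of a
genome for it, and turns each match into a screened, ranked candidate
gene region. Because the scan happens at the DNA level, it can also
tolerate plant-organelle C-to-U RNA editing, where the genome differs
from the mRNA it encodes — the scenario in which homology methods fail
outright. The intended users are molecular biologists hunting for
"missing" family members in newly sequenced or organellar genomes.

## The method

1. **Compile** (`parse_tag()`, `reverse_translate()`). Each fixed
   residue becomes a 3-nt *box* whose per-position nucleotide sets are
   the union of its codons; each run of `k` wildcards becomes a
   frame-preserving gap of `3k` nt. The IPK tag compiles to

   ```
   CC{T,C,A,G}---------GA{T,C}---AA{A,G}---GG{T,C,A,G}
   ```

   with per-placement background match probability
   (1/16)(1/32)(1/32)(1/16) = 2⁻¹⁸.
2. **Scan** (`scan_sequence()`, `scan_fasta()`). Every placement on
   both strands, with configurable mismatch/skip/swap budgets and
   optional editing-aware matching (`editing_policy()`); an exhaustive
   oracle (`brute_force_scan()`) defines the semantics and backs the
   test suite.
3. **Post-process** (`extract_candidate()`, `translate_window()`,
   `filter_wildcards()`, `stop_free_span()`). A ~1200-nt window around
   each hit is translated in the tag-anchored frame; candidates must
   carry the fixed residues exactly, wildcard residues from
   {L,V,T,M,I,A,S,G,C}, and a long stop-free span around the tag.
4. **Rank** (`smith_waterman()`, `tag_correspondence()`). Candidates
   are aligned to reference kinases (BLOSUM62, affine gaps 11/1) and
   checked for tag-on-tag correspondence.

A synthetic-genome module (`simulate_genome()`) plants
codon-randomized tag instances, with recorded truth, into random
backgrounds — including simulated editing corruption — and is the
package's entire test data supply.

## Worked example

```r
library(tagscan)

pat <- reverse_translate(parse_tag("P-XXX-D-X-K-X-G"))
print(pat)
#> Degenerate nucleotide pattern ( 4 boxes ):
#>   CC{T,C,A,G}---------GA{T,C}---AA{A,G}---GG{T,C,A,G}
#>   12 constrained positions, 8 anchored

# a 20-kb synthetic genome with one minus-strand planted tag
sim <- simulate_genome(simulation_spec(
  seed = 7, n_records = 1, record_length = 20000,
  plants = list(list(tag = parse_tag("P-XXX-D-X-K-X-G",
                                     wildcard_allowed = FILTER_ALLOWED),
                     position = 9000, strand = "-"))))
write_simulation(sim, "genome.fa")

refs <- c(KCS1_like = paste0(paste(sample(AMINO_ACIDS, 80, TRUE), collapse = ""),
                             sim$truth$tag_aa,
                             paste(sample(AMINO_ACIDS, 80, TRUE), collapse = "")))
rec <- run_pipeline("genome.fa", "P-XXX-D-X-K-X-G", references = refs)
rec[, c("sequence_id", "start", "end", "strand", "tag_aa",
        "filter_pass", "stop_free_span_aa", "best_reference", "best_score")]
#>   sequence_id start  end strand    tag_aa filter_pass stop_free_span_aa
#> 1    record_1  9001 9027      - PSMIDMKMG        TRUE                19
#>   best_reference best_score
#> 1      KCS1_like         50
```

The planted tag is recovered on the minus strand at its exact 1-based
coordinates; its translation `PSMIDMKMG` carries the four fixed
residues (P, D, K, G) and allowed wildcards, so it passes the filter;
`stop_free_span_aa` is the length of the longest stop-free translated
run containing the tag (here 19 residues — random background codons
stop frequently, a real exon would score in the hundreds); and the
candidate's best local-alignment score against the reference set is
reported. `write_hits_tsv()` / `write_hits_gff3()` export the same
records.

A command-line front end covering each step
(`compile | scan | extract | filter | align | simulate | pipeline`)
is installed at `inst/scripts/tagsearch`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts","tagsearch",package="tagscan"))')" \
    pipeline --tag "P-XXX-D-X-K-X-G" --fasta genome.fa --out hits.tsv
```

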