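# circseam

Circle-specific PCR primer design for circular RNA validation.

## The problem

Circular RNAs (circRNAs) are covalently closed transcripts formed by
back-splicing: a downstream splice donor joins an upstream splice acceptor.
Because predictions from RNA-seq are noisy and pipeline-dependent, candidate
circRNAs are routinely cross-validated by RT-PCR/qPCR before anything else
is done with them. Ordinary primer design does not work for this: every base
of a circRNA is shared with its linear host transcript *except* the
back-splice junction (BSJ). circseam therefore builds, for each predicted
circle, a linear **junction template** — the circle's 3′ flank concatenated
to its 5′ flank —

```
genome:    ----[ start ........ end )----
circle:          5'~~~~~~~~~~~~3'  (end joins back to start)
template:  [ ...last L nt of circle | first R nt of circle... ]
                                    ^ junction at index L
```

and designs primer pairs whose amplicon strictly contains that junction.
Such pairs converge across the BSJ on the circle but point *away* from each
other (divergent) on the linear genome, so only the circular isoform yields
a product.

## What it computes

* **Parsing** — back-splice coordinates from CIRI2, find_circ,
  CIRCexplorer2, DCC, circRNA_finder, KNIFE, mapsplice or plain BED, all
  normalized to 0-based half-open records (`parse_records()`, up to 100
  records per submission).
* **Templates** — up to 150 nt per flank by default, clamped at one full
  circle for short circles (`build_templates()`).
* **Primers** — exhaustive window enumeration with GC (0.20–0.80),
  homopolymer (≤ 4), hairpin and self-dimer screens, and a nearest-neighbor
  melting temperature: unified 1998 NN parameters with the entropy salt
  correction 0.368 (N−1) ln[Na⁺] and Tm = 1000·ΔH / (ΔS + R ln(C_T/4)) −
  273.15. Candidates of 15–20 nt (optimum 19) are paired into amplicons of
  150–200 nt that must span the junction, ranked by
  `w_len·|len−19| + w_tm·|Tm−60| + w_gc·|GC−0.5|` per primer plus
  `0.5·ΔTm` per pair, and the top 4 sets per circle are reported.
* **Specificity** — each pair is mapped back to the linear locus (± 5 kb);
  convergent exact placements with a product ≤ 5 kb are flagged.
* **Conditions** — per pair: annealing at min(Tm) − 3 °C, extension
  30 s/kb (floor 30 s), 35 cycles, 95 °C denaturation.

Reference genomes come from a local FASTA (plain or gzip) or an NCBI
assembly accession fetched once into a cache (`open_genome()`).

## Worked example

Everything below is generated in code — no downloads:

```r
library(circseam)

fx <- make_fixture(fixture_spec(seed = 7, n_circles = 3), tempfile("fx"))
genome <- open_genome(fx$genome)
batch  <- parse_records(fx$calls$bed)   # any of the 8 dialects works
design <- design_primers(batch, genome) # default design_config()

glance(design)
#> # A tibble: 1 x 7
#>   n_records n_templates n_designed n_failed n_pairs mean_pair_penalty mean_product_size
#> 1         3           3          3        0      12              7.83              160.

tidy(design)[1, c("circ_id", "fwd_seq", "rev_seq", "product_size",
                  "annealing_temp")]
#> # A tibble: 1 x 5
#>   circ_id  fwd_seq             rev_seq              product_size annealing_temp
#> 1 circ_001 ACGCTCCCACTAGGACGCC TGCTGTTGCCGTGGACGATG          152           54.9
```

Each row is one ranked primer set: the forward 19-mer sits in the donor-side
flank, the reverse 20-mer (given 5′→3′) binds the acceptor-side flank, the
152 nt amplicon contains the junction, and 54.9 °C is the recommended
annealing temperature (3 °C below the cooler primer's Tm of 57.9 °C).
`write_report(design, "out/")` writes `primers.tsv`, `templates.fasta`,
`failures.tsv` and a run log; `autoplot(design)` draws the primer map.

From the shell, the same run is

```sh
inst/cli/circseam design --input calls.bed --genome genome.fa --out out/
inst/cli/circseam fixture --seed 7 --out fx/
```

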