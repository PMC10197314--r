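---
title: "Designing circle-specific primers across the back-splice junction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing circle-specific primers across the back-splice junction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circseam)
```

## The design problem

A circRNA shares every internal base with its linear host transcript. The
one sequence feature unique to the circle is the back-splice junction
(BSJ), where the downstream donor is joined to the upstream acceptor.
circseam validates predictor calls by building a linear *junction template*
for each circle — the last `shift_left` nucleotides of the circle followed
by its first `shift_right` nucleotides — and then running ordinary linear
primer design with one extra, non-negotiable constraint: the amplicon must
contain the junction strictly in its interior. On the circular transcript
such a pair amplifies normally; on the linear genome the same two oligos
point away from each other, so no product forms. This is the standard
divergent-primer strategy for RT-PCR/qPCR validation of circRNAs, made
systematic.

Coordinates are handled internally as 0-based half-open intervals (the BED
convention); each supported predictor dialect (CIRI2, find_circ,
CIRCexplorer2, DCC, circRNA_finder, KNIFE, mapsplice, plain BED) is
converted at exactly one site, so a 400 nt circle is 400 nt regardless of
which caller reported it.

```{r workflow}
fx <- make_fixture(fixture_spec(seed = 7, n_circles = 3), tempfile("fx"))
genome <- open_genome(fx$genome)
design <- design_primers(parse_records(fx$calls$bed), genome)
glance(design)
```

## Template construction

For a plus-strand record `[start, end)` the template is
`genome[end - L, end) + genome[start, start + R)` with the junction at
index `L`; minus-strand circles are built on the transcribed strand.
`L` and `R` default to 150 nt and are clamped at the circle's span: a
circle shorter than the window contributes at most one full copy of itself
per flank. Wrapping further would place a second copy of the junction
inside the template and create artifactual primer sites, so it is never
done. Equivalently, every template is a substring of the doubled circle
sequence of length at most twice the span — that equivalence, and the
invariance of designs under mirroring the whole genome, are checked
property-style in the test suite.

Templates are built from contiguous genomic flanks. Intron structure
(BED12 blocks) is deliberately ignored: the input contract is a pair of
junction coordinates, and for multi-exon circles whose terminal exons are
shorter than the flank window the template can include intronic sequence.
This is a known approximation; primers that happen to fall in such a
region will still PCR on genomic DNA controls, which the linear
specificity check partially guards against.

## Thermodynamics

Melting temperatures come from nearest-neighbor summation with the unified
1998 parameter set (ΔH in kcal/mol, ΔS in cal/(mol·K), terminal A·T/G·C
initiation penalties), the monovalent-salt entropy correction
`0.368 (N − 1) ln[Na+]`, and the two-state formula

    Tm = 1000 ΔH / (ΔS + R ln k) − 273.15,   k = C_T / 4,

with `C_T` the total strand concentration (default 50 nM) and `[Na+]`
defaulting to 50 mM. Palindromic primers are detected automatically and
take the symmetry correction (ΔS − 1.4) with `k = C_T / 2`. The engine is
deterministic to far below 0.01 °C; the tests pin it to an independently
written per-step summation oracle (within 0.05 °C over 1000 random
primers) and to a frozen reference value for a documented 19-mer
(53.2938 °C) computed once with an external NN implementation before this
engine was written.

No divalent-cation or dNTP correction is applied. That makes the default
Tm scale a conservative (low) estimate relative to engines that fold Mg²⁺
into an effective monovalent concentration; users matching a Mg-corrected
workflow should either raise `monovalent_salt` to their effective value or
widen the Tm window.

## Candidate screens and pairing

Every template substring of 15–20 nt (optimum 19) is considered in both
orientations; nothing is sampled, so the survivor set is exactly the set
passing all screens (the tests verify this against a brute-force
re-filter). Screens, in order: no ambiguous base; longest homopolymer
≤ 4; GC in [0.20, 0.80]; Tm in [57, 63] °C; self-dimer ≤ 8 total
Watson–Crick matches over all ungapped antiparallel self-alignments and
≤ 4 in any run anchored at the 3′ terminus; hairpin stem ≤ 4 with loop
≥ 3. The dimer/hairpin scores are plain pair counts rather than free
energies — cheap, deterministic, and adequate for screening; partition-
function thermodynamics is explicitly out of scope.

Pairs must have product size in [150, 200] nt, |ΔTm| ≤ 3 °C, and the
junction strictly inside the product. Candidates may themselves overlap
the junction point; only the product must contain it. Ranking uses

    pair_penalty = Σ_primer ( 1.0·|len − 19| + 1.0·|Tm − 60| + 10.0·|GC − 0.5| ) + 0.5·|ΔTm|

with ties broken deterministically by (penalty, product start, forward
sequence), and the best 4 pairs per circle are reported. The weights mirror
common primer-design practice: one penalty unit per nt of length deviation
or per °C of Tm deviation, with GC up-weighted so that a 10 % GC excursion
costs like 1 °C. "Primer sets" means ranked alternative pairs for the same
junction, not multiplex groups.

The Tm window default (57/60/63 °C) is the one genuinely free choice in the
configuration — the length, product-size, flank and set-count defaults are
the conventional submission-form values — and it is deliberately the common
qPCR default. Under it, ≤ 20-mers on uniform 50 %-GC sequence pass only in
locally GC-enriched windows, so on i.i.d. synthetic genomes roughly a
quarter to a third of circles come back "no primers found". Real genomes
are GC-heterogeneous and real batches fare better; the failure path is a
first-class outcome (`failures.tsv` with a reason), not an error.

## Linear-genome specificity

A junction-spanning pair is divergent at its own locus by construction, so
the residual risk is repeat-mediated: a copy of one flank in convergent
orientation nearby. `linear_specificity_check()` exact-matches both oligos
against the locus ± 5 kb on both strands and fails the pair if any
convergent placement implies a product ≤ 5 kb. Exact matching (no
mismatches) and the windowed search radius are deliberate limits — this is
a local sanity check, not a genome-wide BLAST, and is documented as such.

## Thermocycling recommendations

Annealing at `min(Tm_f, Tm_r) − 3 °C` (rounded to 0.1), extension
`max(30, ceil(size/1000)·30)` s, 35 cycles, 95 °C denaturation. These are
bench heuristics, configurable via `ta_offset` and `ext_per_kb`, and make
no claim beyond being a sensible starting gradient.

## The synthetic fixture generator

`make_fixture()` emulates the *inputs* of a validation study: a random
genome (i.i.d. bases at a target GC, default 0.5) with circles planted at
known coordinates (default 10 circles of 200–2000 nt on a 10 kb contig,
matching a typical validation batch in size), serialized in all eight
dialect conventions plus a canonical truth table, all reproducible from one
integer seed. Optionally it plants a convergent copy of a circle's acceptor
flank ~1 kb downstream to exercise the specificity check. It does **not**
emulate splice-site motifs, exon structure, repeat families or GC isochores
— so green tests demonstrate the correctness of coordinate handling,
thermodynamics, screening, pairing and reporting, not the expected design
*yield* on any real genome.

## Numerical and degenerate-input choices

* IUPAC codes other than N are mapped to N with a warning; windows
  containing N are unconditionally rejected; records whose whole template
  is N are dropped with a reason.
* Strand `"."` is accepted as `"+"` with a warning; duplicate records
  (same chrom/start/end/strand) keep their first occurrence; submissions
  are truncated at 100 records with a warning (an error under `strict`).
* All ranking ties are broken lexicographically, so identical inputs give
  byte-identical `primers.tsv` — asserted as a test.
* Problem sizes in the test suite are chosen for coverage per second:
  oracle sweeps use 1000 random primers, pairing oracles use templates of
  300–500 nt, and the junction-spanning property runs 1000 fixture circles
  (ten seeds × 100) without the specificity pass.

## Known limitations

* No genome-wide off-target search and no probe (hydrolysis) design.
* No exon-structure-aware mature-sequence reconstruction; flanks are
  genomic.
* Dimer/hairpin screens count base pairs, not ΔG.
* The KNIFE and mapsplice column conventions in the wild vary by version;
  the parsers implement one documented layout each and freeze it in golden
  tests, so other variants may need `format =` plus a pre-formatting step.
* Accession-mode genome retrieval requires network once; every test and
  all documentation examples run fully offline.
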