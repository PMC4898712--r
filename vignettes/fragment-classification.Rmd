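---
title: "Classifying fragmented rRNA reads and modelling PCR bias with fragtax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying fragmented rRNA reads and modelling PCR bias with fragtax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragtax)
```

## Why fragment-aware classification

Amplicon pipelines assume reads that all start at a primer and cover the
same variable regions. Direct sequencing of reverse-transcribed SSU rRNA
(random-primed cDNA) breaks every one of those assumptions: fragments start
anywhere on the molecule, come from both strands after second-strand
synthesis, vary widely in length, and may cover only conserved sequence.
`fragtax` classifies such fragments against a reference taxonomy and, on
the flip side, quantifies *why* amplicon data misrepresents some taxa:
divergent primer-binding sites and unequal per-cycle amplification
efficiencies.

## The classification model

**Quality salvage.** A read whose quality collapses locally is not
discarded; every maximal run of bases with Phred quality ≥ `min_quality`
(default 20) and length ≥ `min_length` (default 50 nt) becomes a sub-read
carrying its parent coordinates. Maximal-run extraction was chosen over
sliding-window averaging because it is the simplest scheme in which no
retained base is ever below threshold, which keeps the downstream word
statistics honest. Ambiguous bases (`N`) are not treated as quality
failures; instead sub-reads with more than 10% `N` are dropped at the
filter stage, keeping base-calling ambiguity separate from quality
trimming.

**Dereplication.** Exact string identity on the forward strand only.
Strand canonicalisation is deliberately deferred to the search stage so
that dereplication is order-independent and trivially exact; the cost is
that a fragment and its reverse complement dereplicate separately, which
only forfeits a little compression.

**Word similarity.** The similarity of query `q` to reference `r` is

$$S(q, r) = \frac{|W_k(q) \cap W_k(r)|}{|W_k(q)|},$$

the fraction of the query's distinct k-mers present in the reference.
This is asymmetric by design: fragments are 60–400 nt against ~1.5 kb
references, and normalising by the query makes an exact substring score
1.0 where Jaccard would score ~0.1. Words containing non-ACGT characters
contribute nothing. The default `k = 8` balances two pressures: long
enough that a shared word is meaningful against a 1.5 kb reference
(expected chance occurrences per reference ≈ 1500/4^8 ≈ 0.02), short
enough that a 100 nt fragment still carries ~93 words, so similarity is
finely enough grained for the LCA window to work. Both the query and its
reverse complement are always searched, because random-primed RT plus
second-strand synthesis yields reads from both strands.

**Taxonomy projection.** All hits within `top_window = 0.02` of the best
similarity vote, and the read receives the lowest common ancestor of the
voting references' lineages over the fixed six-rank ladder
domain→phylum→class→order→family→genus. Genus is the deepest rank carried
because short fragments cannot reliably resolve further. Fragment
similarities are coarse (a 100 nt read moves in steps of ~1/93), which is
why near-ties share the vote instead of letting one hit decide. Reads
whose best similarity falls below `min_similarity = 0.40` are *reported*
as unclassified rather than silently dropped — in rRNA surveys the
unclassified fraction is itself a finding, and hiding it would bias every
density upward.

**Abundance.** Read density is the percentage of classified dereplication
weight per taxon. Tables can be normalised over everything (`group =
"all"`) or within each domain (`"within_domain"`), the latter mirroring
the common two-level presentation in which phylum densities are percent
contributions to their domain. Assignments shallower than the requested
rank pool under `"unclassified <parent>"` so that each group still sums
to 100.

**Variable-region screening.** Fragments covering only conserved rRNA
stretches carry little signal. Against a user-supplied interval map
(BED-like, 0-based half-open) the pipeline measures the fraction of each
read's aligned reference footprint inside variable regions and flags reads
at `min_overlap = 0.25`. The flag is annotation, not a filter: discarding
conserved-region reads would distort densities, and downstream users can
weight or drop flagged reads themselves.

## The banded aligner

Per-read event counting (primer audit, region screening) needs actual
alignments. `align_pair()` is a semi-global Gotoh alignment — query
global, reference local, since fragments map inside near-full-length
references — with scores match +1, mismatch −1, gap open −2, gap
extension −1 (a gap of length $L$ costs $2 + L$). The band (half-width 32)
is centred on the most frequent shared-word diagonal; when seeding fails
or the band admits no query-global path (repetitive sequence can mislead
the seed), the computation silently falls back to the unbanded matrix. The
implementation is compiled (Rcpp); tests verify banded scores against an
independent full dynamic programme across hundreds of random pairs.

## Chimera detection

The amplicon pipeline screens unique reads against the reference index:
for each breakpoint `b` (scanned at word-length steps, ≥ `min_segment =
60` nt from each end) it computes the best prefix-parent and suffix-parent
word similarities, and flags the read when
`max_b min(S_prefix, S_suffix)` exceeds the best single-reference
similarity by `min_improvement = 0.10` *and* the two parents differ.
Reference-based detection (rather than de-novo abundance ranking) was
chosen because the pipeline already holds a reference index, and it gives
an exactness guarantee: a read that is a substring of one reference has
`S_full = 1` and can never be flagged. Both strands are scanned so the
verdict is invariant to reverse complementation. The RT-fragment mode
skips this stage entirely — chimeras are a PCR artefact, and random
fragments legitimately resemble joins of conserved segments.

## Primer-site auditing

Primer windows are located on *references*, not raw reads: each reference
is scanned for the best window of each primer (reverse primers as their
reverse complement) under IUPAC-aware Hamming distance, with a generous
default cap of 5 mismatches since heavily divergent sites are precisely
the interesting ones. Reads are then aligned to their best-matching
reference and events are read off the alignment columns inside each fully
covered window: mismatches are counted between the aligned read base and
the **primer** base projected onto the window (so a read identical to a
reference whose site diverges from the primer at six positions reports six
mismatches — the quantity that predicts amplification failure), deletions
are primer positions the read lacks, and insertions count when flanked by
in-window reference positions. Per-taxon roll-ups report **both** ratio
orientations — reads-with-site per event, and events per read-with-events
— because both conventions circulate in the field and they are not
reciprocals of the same quantities; neither is privileged.

## The PCR/qPCR simulator

Each mock-community template `i` has input copies $N_i$ and a per-cycle
duplication probability $e_i \in [0,1]$. Deterministic amplification is
the closed form $N_i(1+e_i)^n$; stochastic mode duplicates each molecule
independently (binomial per cycle, switching to a moment-matched normal
approximation above $10^9$ molecules purely for arithmetic range). The
efficiency is constant across cycles — no plateau term — because ratios
are interpreted at fixed cycle numbers and a saturation model would add
parameters nothing in the data constrains. The qPCR read-out is
$Ct = b + m\,\log_{10}(\text{copies})$ plus optional Gaussian noise;
`fit_standard_curve()` is ordinary least squares over a dilution series
(default six 10-fold points spanning $10^3$–$10^8$ copies), reporting
$R^2$ and efficiency $(10^{-1/m}-1)\cdot 100\%$; `quantify()` inverts the
curve. The default community mirrors a five-clone mixture
(A9:C10:F10:E3:E9 = 1:3:8:2:10) with 10/20/30-cycle arms and a 3
biological × 3 experimental replicate grid. Per-clone efficiencies are
free inputs: the defaults (0.95, 0.70, 0.90, 0.85, 0.80) were chosen once
as plausibly spread values that make the bias mechanism visible — with
$e_A > e_B$ the post-PCR A/B ratio grows as $((1+e_A)/(1+e_B))^n$,
strictly in $n$ — and the simulator makes no claim to reproduce any
particular measured community.

## What the synthetic data does and does not emulate

`generate_reference_set()` mutates a random root sequence independently
per taxon to an exact divergence (default 0.10 over 1500 nt), with
lineages splitting at a configurable rank. `fragment_reads()` draws each
read's source by the declared proportions, its start uniformly, its length
from a uniform 60–400 nt distribution (echoing in-silico fragment studies
of random-primed RT; lengths clip at the reference end, so a small tail of
shorter reads exists just as in real libraries), and reverse-complements
with probability 0.5. `apply_errors()` adds per-base substitutions and
indels and emits Phred qualities with optional low-quality dropout
stretches — the feature the salvage stage exists for.

Passing tests on this generator demonstrate correctness of the machinery
— composition recovery within binomial error, ≥99% genus accuracy at 10%
reference divergence — not performance on real data: the generator has no
homopolymer-specific error structure, no priming-site sequence bias, no
conserved/variable rate heterogeneity along the molecule, and its
reference databases are tiny and perfectly matched to the sample. Real
surveys face reference incompleteness, which is exactly why the
unclassified fraction is a first-class output.

## Numerical and scale choices

Test-suite and acceptance problem sizes — 20,000 fragments for
composition recovery, 1000 pure reads and 200 constructed chimeras for the
chimera suite, 500 random pairs for alignment oracle equivalence — were
chosen so the binomial error bars are tight enough to be meaningful while
a full run stays in the minutes range on a single core. Ties in similarity
ranking break lexicographically by reference id; ties among equally
mismatched primer windows go to the leftmost; the degenerate flat
standard curve (slope ≥ −10⁻⁶) is flagged invalid rather than returning
infinite efficiencies. All generator functions take explicit seeds and are
bit-reproducible; the classification path itself contains no randomness.

## Known limitations

- Word similarity saturates at 1.0, so references more similar than
  `1/|W_k(q)|` to each other cannot be distinguished by score on short
  queries; the LCA window handles this by design (the read shallows to the
  shared rank).
- Low-complexity fragments carry few distinct words and can score high
  against any reference sharing a repeat; real pipelines should length-
  and complexity-filter upstream (the `N`-fraction filter does not catch
  repeats).
- Chimera detection is limited to two parents and is only run in amplicon
  mode.
- The simulator's efficiency-constant model ignores late-cycle plateau;
  ratios at 30 cycles of a real reaction compress relative to the model.
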