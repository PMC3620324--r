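---
title: "Designing predator DNA removal for diet metabarcoding"
author: "preyblock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing predator DNA removal for diet metabarcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preyblock)
```

## Scope and model

PCR-based diet analysis of a generalist predator amplifies a COI barcode
fragment from gut contents with versatile primers; the predator's abundant,
high-quality template out-competes degraded prey DNA unless it is removed.
`preyblock` covers the in-silico side of the two removal strategies —
restriction-enzyme screening and blocking-primer design — and the
clone-library processing that follows (OTU delineation, pseudogene and
identity QC). Wet-lab concerns (digestion conditions, primer chemistry
beyond the 3′ spacer annotation, chimera detection, external database
searches) are out of scope; hooks accept pre-computed exclusion lists where
an external tool would normally contribute.

## Restriction screening

A recognition motif is matched under IUPAC set-intersection semantics: a
motif letter matches a target letter iff their expansion sets intersect.
This is deliberately optimistic about cutting — an ambiguous target base
that *could* be cut counts as a hit — because the screening goal is to avoid
losing prey templates, so possible cutting must be flagged. Both strands are
scanned by default (restriction enzymes act on duplex DNA; the sources this
screen emulates are silent on the point), with palindromic motifs reported
once. Effective recognition length is bounded to 6–15 bp, runs of N counting
toward the length (`CCANNNNNNTGG` = 12).

Enzymes that cut the predator are ranked by the **unweighted** mean of
per-group prey cutting frequencies rather than the pooled frequency: prey
groups differ greatly in library size (hundreds of decapods versus a few
hundred gastropods), and a pooled mean would let the large groups swamp the
small ones that the screen is meant to protect. Ties resolve
lexicographically by enzyme name, making the ranking deterministic.

Cut positions within a site are rarely decisive for screening, so
`cutOffset` defaults to 0 (the 5′ boundary of the matched site) and fragment
predictions are documented as approximate — adequate for interpreting gel
bands of a partial digest.

## Conservation profiling and the anchor

Per-column frequencies count unambiguous A/C/G/T only; gaps and ambiguity
codes are excluded from numerator and denominator, matching the convention
of published per-position tables that sum to 100 % over the four bases. A
column with nothing to count is reported as undefined (`NA`), never as
zeros. Shannon entropy h(x) = −Σ p log p is 0 at conserved columns and
maximal (ln 4 nats, or 2 bits) at equifrequency. The log base defaults to e
but is exposed, since only the *ordering* of columns matters for anchor
selection and that is base-agnostic.

The blocking primer's specificity comes from its 3′-terminal anchor (k = 4
columns by default, following the four-site predator-specific tetramer that
motivates the default; k is a parameter). For prey group *g*, the
probability that a template mismatches the anchor somewhere is

\[ P_g(\text{mismatch}) = 1 - \prod_{i=1}^{k} P_g(b_i \text{ at column } i), \]

with b the predator bases and columns treated as independent. Candidate
windows are ranked by the **minimum over groups** of this probability — the
worst-case prey group decides, since a primer that blocks even one group is
a failed design — with mean entropy over the window and then smaller start
column as tie-breakers only.

```{r anchor}
pfms <- anchorSiteFrequencies()
anchor <- anchorWindow(640, 643, "TCTT")
round(100 * groupMismatchProbabilities(pfms, anchor), 3)
```

## Blocking-primer geometry

The primer spans contiguously from the versatile-primer overlap into
predator-specific sequence, 3′ end at the anchor, with exactly
`overlap` bases (default 10) inside the versatile region and total length
bounded by `maxLen` (default 30; designs aim below 30 bp to keep melting
temperatures low — Tm itself is not modelled). When the versatile region
lies on the higher-column side of the anchor the primer is emitted 5′→3′ on
the reverse strand, competing with the reverse versatile primer; the
mirrored geometry yields a forward primer. Published descriptions of the
overlap ("the last 10 bases") are ambiguous about which end is "last"; the
geometry here places the overlap at the primer end nearer the versatile
region, which is the only layout consistent with the 3′ end sitting at the
anchor, and the overlap length is a parameter rather than a guess. The
elongation-blocking 3′ modification (Spacer C3) is metadata on the design —
never a base — and ordered primer sequences can be re-checked against the
length/alphabet constraints with `validateBlockingPrimer()`.

Per-prey mismatch profiling is IUPAC-aware with mismatch = empty
intersection: an N in a prey sequence never counts as a mismatch, which is
conservative in the direction of *flagging* the risk that the primer blocks
that prey; a gap always counts. Alignment coordinates are 1-based closed
intervals throughout, and column numbering is a property of the supplied
alignment — the package does not assume where column 1 of the barcode
fragment falls relative to the forward primer.

## OTU delineation

Uncorrected p-distances use pairwise deletion (columns with a gap or
ambiguity in either member of a pair are dropped, and the number of compared
columns is recorded); whether the tools this emulates deleted such columns
pairwise or globally is not documentable, so the rule is stated here rather
than claimed as a reproduction. "Furthest neighbor" is taken as complete
linkage — inter-cluster distance is the maximum pairwise member distance —
the definition used by the standard sequence-clustering tools. Merging
proceeds while the smallest complete-linkage distance is ≤ the threshold;
ties resolve to the lexicographically smallest pair of minimum member ids,
so the partition is deterministic. Complete linkage has no height
inversions, so one agglomeration serves the whole threshold grid.

The qualitative notion of the OTU count "becoming stable" is
operationalized as the longest maximal run of equal counts across the
threshold grid (earliest run on a length tie); the stable threshold is the
run's start. The full scan is returned so users can apply judgment, as
practitioners typically quote a stable *range* (e.g. 5–10 %) rather than a
point. Representatives minimize the sum of distances to their cluster
co-members (ties to the smallest id).

## Clone-library QC

Pseudogene filtering translates the three forward frames under the
invertebrate mitochondrial genetic code (the correct code for COI of
decapod/gastropod prey; configurable — AGA/AGG are serine there, not stops)
and passes a sequence iff some frame is free of internal stops, terminal
partial codons ignored and a stop in the final complete codon not counted
as internal. True indel-based frame-shift calling needs a curated reference
alignment and is excluded; a frame-shifted copy generally shows stops in
every forward frame and is caught by the same rule. Sequences under 60 nt
are reported `too_short`, not judged.

Identity assignment replaces an external database search with a
deterministic local computation: semi-global (ends-free) pairwise alignment
with fixed scores (match +1, mismatch −1, gap −2), identity = matches /
aligned columns. The best reference is the highest-*scoring* alignment —
ends-free alignments to unrelated references can form short perfect
overlaps, so raw identity cannot rank references — and the species bound
(default 0.98) is inclusive, with a 1e-9 numeric guard so an identity of
exactly 98 % assigns. This is a documented substitute for a BLASTN-vs-
database step, not a reproduction of any particular tool's identity
definition.

## Synthetic data: what it emulates, and what it does not

The generators produce every input class under explicit seeds, each call on
its own RNG stream with the caller's state restored.

- `genAlignmentFromPfm()` draws rows i.i.d. per column from a frequency
  matrix. It reproduces column-wise composition (so empirical frequencies
  and the anchor mismatch probability converge to their analytic values) but
  has no phylogenetic correlation between columns or rows.
- `genClusteredSequences()` models species as ancestors derived from a
  common base sequence at the inter-cluster divergence floor
  (rejection-checked to stay ≥ `interDiv`, default 12 %), with members
  substituted at `min(Binomial(len, intraDiv), floor(len * intraDiv))`
  sites. The truncated draw concentrates member divergence near the
  intraspecific cap (default 2 %), which reproduces the regime real barcode
  libraries show — low thresholds oversplit species, then the count
  plateaus — while guaranteeing the maximum intra-cluster pairwise distance
  is ≤ 2·`intraDiv`, so recovery tests are analytic. Substitutions only: no
  indels, no codon structure, no transition/transversion bias.
- `genPredatorPreyLibrary()` plants a concrete instance of a (possibly
  degenerate) recognition motif exactly once in the predator and at a
  configured rate in prey, rejection-checking against accidental occurrences
  on either strand.
- `genCloneLibrary()` draws stop-free coding sources, derives clones by
  stop-avoiding substitution (so clean clones stay clean by construction),
  and converts a chosen subset into pseudogene mimics by planting a stop in
  every forward frame. Real pseudogenes also show indels and elevated
  divergence; only the stop-codon signature is modelled, which is exactly
  the signature the filter detects.

Passing tests on these generators therefore demonstrate the correctness of
the algorithms under their stated models — not the field performance of any
particular primer or enzyme on real gut contents, which depends on the
reference library and on amplification biases outside this package's scope.

## Numerical choices and problem sizes

Frequency rows read from published tables are renormalized to sum to 1
(printed percentages round to one decimal); the row-sum tolerance is 5 %
on input and 1e-9 after construction. Entropy treats 0·log 0 as 0.
Probabilities and distances are compared with exact arithmetic where
possible (counts divided by counts); the only epsilon in the package is the
1e-9 inclusivity guard at the assignment bound. Test and validation runs
use library sizes a desk study would: oracle equivalence on hundreds of
random sequence/motif pairs at ≤ 200 bp, exhaustive clustering oracles at
n ≤ 8 over 200 random matrices, frequency recovery at 10,000 simulated
rows, and cluster-recovery scans at 2–10 species of 5 members each on
658-bp sequences.

## Known limitations

- Cutting frequencies and mismatch probabilities are only as good as the
  reference library behind the frequency table; small or biased libraries
  understate prey-side risk.
- The independence assumption across anchor columns ignores codon structure
  (third positions co-vary with the amino-acid constraint on the first
  two).
- No thermodynamics: Tm, dimers and hairpins must be checked with a primer
  tool before ordering.
- Complete-linkage OTUs at a fixed threshold are a proxy for species;
  the plateau detector informs, but does not replace, taxonomic judgment.
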