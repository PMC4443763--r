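---
title: "Methods: design, simulation and decoding of overhang-based DNA block libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: design, simulation and decoding of overhang-based DNA block libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockshuffler)
```

## The assembly system

Overhang-based DNA block shuffling builds combinatorial gene libraries by
one-pot ligation of short double-stranded DNA "blocks". Each block is a
16-bp duplex core with a 2-nt 5' overhang; in an assembled gene the block
contributes an 18-nt repeat unit — six codons encoding one hexapeptide. All
blocks share one overhang pair so any block can ligate after any other,
giving a combinatorial library whose length varies in multiples of 18 bp.
Two constraints make the chemistry work:

* **Non-palindromic overhangs.** A dinucleotide equal to its own reverse
  complement (AT, TA, GC, CG) anneals in either orientation, destroying
  directionality. `validate_overhang()` rejects those four and accepts the
  other twelve; the default library chemistry is AG-TC (we write the bottom
  strand 3'→5', as the pair is conventionally drawn).
* **Single-ended adapters.** The 5' and 3' adapters are ligation-competent
  on exactly one side, so they cap concatemer growth and define the PCR /
  sequencing handles. In the model they also cannot dimerize with each
  other directly (see below).

Blocks are *degenerate*: synthesized with IUPAC mixed bases so one oligo
pair encodes many concrete sequences. The design restricts all encoded
hexapeptides to a ten-residue alphabet (Ala, Asp, Glu, Gly, Ile, Leu, Pro,
Ser, Thr, Val) and follows binary patterning: each hexapeptide position is
specified only as polar (P) or nonpolar (N), which is enough to bias
secondary structure (helix, strand, loop).

## Degenerate codon search

`find_degenerate_codons()` answers: which degenerate codons encode exactly
a given residue set, nothing else, and no stop? It enumerates all
15^3 = 3375 IUPAC codons, keeps the admissible ones (expansion translates
inside the target, stop-free) and finds all minimal-cardinality covers by
depth-first search with suffix-union pruning. Solutions are returned in
lexicographic order for reproducibility. `build_block()` picks one codon
per position from the minimal covers, preferring the smallest expansion
(synthesis economy) and then lexicographic order; the `variant` argument
cycles deterministically through alternatives so that many distinct blocks
can be derived from one pattern.

Because the 2-nt overhang is the first 2 nt of the 18-nt repeat unit, the
first codon of an in-frame block must literally start with the overhang
dinucleotide. Under AG-TC this forces the first codon into AGN, i.e. Ser
(AGC/AGT) for a polar first position — a genuine constraint of the
chemistry, which is why the shipped patterns all start with P. Passing
`overhang = NULL` to `build_block()` lifts the constraint and gives pure
codon arithmetic (useful for exploring codon designs that are not meant to
be ligated).

The binary patterns shipped as defaults (helix `PNNPPN`, strand `PNPNPN`,
loop `PPPPPP`) are placeholders with the right periodicity character, not a
reproduction of any published design table; they are configurable, as is
the polar/nonpolar partition (default P = {D, E, S, T},
N = {A, G, I, L, P, V}, the standard hydropathy classes).

## The synthetic study-scale catalog

The sequenced library we emulate comprised 168 degenerate oligo pairs
corresponding to 8288 concrete DNA blocks over the ten-residue alphabet.
The actual 168 oligo sequences are not redistributed here;
`synthetic_catalog()` instead *generates* a catalog
with the same aggregate shape:

* 168 blocks — 56 helix, 56 strand, 56 loop patterns;
* exactly 8288 distinct concrete expansions (91 blocks of 64 = 2^6
  expansions and 77 of 32 = 2^5, mixing fully degenerate blocks with
  blocks having one concrete position);
* a shared AG-TC overhang in frame (every unit starts AG);
* ten residues exactly;
* pairwise expansion-disjoint blocks, so every concrete 18-mer identifies
  one block and decoding is unambiguous by construction.

Disjointness comes from a fixed codon menu in which all variants of a
class have non-overlapping expansions (e.g. polar variants GAS = {GAC,GAG}
and WCC = {ACC,TCC}); two blocks differing in any menu choice then share no
concrete sequence. The catalog is deterministic — no RNG — and clearly
synthetic: it reproduces the published catalog's statistics, not its
sequences.

## Ligation model

`simulate_ligation()` implements discrete random end-joining to
exhaustion: every ligatable end is equally reactive, and at each step one
chain with an open right end and one with an open left end are chosen
uniformly and joined. The model excludes circularization (self-joining) and
direct adapter-adapter dimerization; both are flagged limitations rather
than claims about the chemistry — mono-phosphorylated adapters suppress but
do not abolish these events on the bench. There are no kinetics, no
mis-annealing and no chimeras. This is the simplest model that reproduces
the ladder-like length distribution seen on gels: with the bench
stoichiometry of 1:8:1 (5' adapter : block : 3' adapter) the simulated
complete products have close to 8 blocks on average (mass balance: all
blocks distribute over ≈ min(n5, n3) capped products) and a geometric-like
length profile. Mass is conserved exactly — every input block ends up in
exactly one product — and directionality is structural: an inverted block
cannot occur in-model, mirroring what non-palindromic overhangs enforce
chemically. The engine is a small C++ loop (Rcpp) driven by R's RNG, so
`set.seed()` makes runs reproducible.

Each block molecule carries a concrete sequence drawn uniformly from its
degenerate expansion set, which models equimolar base mixing during
synthesis.

## Diversity estimation

`expected_distinct(N, K)` is the classic occupancy expectation
`K (1 − (1 − 1/K)^N)`, computed as `K · (−expm1(N · log1p(−1/K)))` so that
astronomically large `K` (e.g. `8288^11 ≈ 1.2e43`) neither overflows nor
collapses to 0. `diversity_profile()` applies it per concatemer length:
the input is stated in blocks, so `N_n = total · fraction(n) / n` converts
to molecules of length `n`, and `K = D^n` with `D` the number of distinct
concrete block expansions, all treated as equiprobable. Ignoring per-block
degeneracy weighting (a 32-expansion block's sequences are individually
twice as likely as a 64-expansion block's) slightly overstates diversity;
at bench scale (1e14 input blocks) the conclusion — about 1e8 to 1e13
non-redundant sequences for concatemers beyond 4 blocks — is insensitive to
this.

## Read simulation

`simulate_reads()` sequences every complete product from the 5' end:
`adapter5 + insert + adapter3`, truncated to `read_length` (150 nt emulates
one MiSeq mate; the pipeline consumes single-end reads, and paired-end
merging is out of scope). Errors are per-base i.i.d.: substitutions to a
uniformly chosen different base at `substitution_rate`, uncalled bases at
`n_rate`. Quality decays linearly from `q_start` (36) to `q_end` (18),
giving a mean around Q27 — the level at which the real run peaked — and the
characteristic end-of-read deterioration. The simulator does not model PCR
bias, indels, chimeric reads, adapter read-through artifacts or
position-dependent error spectra; conclusions from simulated data therefore
speak to the decoder's logic, not to every failure mode of real MiSeq data.

## Decoding chain

`decode_reads()` reimplements the published analysis chain:

1. **Quality trimming** (`trim_reads()`): bases are removed from the 3'
   end until the mean quality of the terminal 50-base window exceeds Q15.
   The cited trimming tool's exact semantics are not published; we use
   window-mean aggregation with step 1 on the 3' end only, and expose both
   parameters. Reads shorter than the window (or with no qualifying
   window) are kept intact and flagged rather than destroyed.
2. **N filter** (`filter_n()`): a read with more than one N is discarded;
   a single N passes (and, if it survives into a codon, translates to X,
   which classifies as missense — an unresolvable codon is an unintended
   residue for screening purposes).
3. **Anchor extraction** (`extract_insert()`): the read must contain exact
   matches of the insert-proximal 8-mers of both adapters, 5' before 3';
   the insert is the sequence strictly between them. No mismatches are
   tolerated inside anchors ("complete matches"); leftmost matches are
   used. The default synthetic adapters are chosen so their anchor 8-mers
   cannot occur inside any catalog expansion (checked over codon bigrams),
   making extraction unambiguous on error-free data.
4. **Block calling** (`decode_blocks()`): the insert is split into 18-nt
   units from position 0 and each unit is matched IUPAC-aware against the
   catalog. Implementation detail: for enumerable blocks this containment
   test is done by hash lookup against the precomputed expansion union
   (identical semantics, vectorized); blocks too degenerate to enumerate
   (over 1e5 expansions) fall back to per-position set matching. A unit
   matching two blocks raises an ambiguity error — a catalog defect, never
   a runtime guess.
5. **Classification** (`classify_inserts()`): precedence wrong_length
   (length not a positive multiple of 18) → nonsense (any in-frame stop) →
   missense (any residue outside the design alphabet) → correct. The frame
   starts at insert position 0, where the 5' adapter junction defines it.
   Missense is alphabet-level, matching "unintended amino acids"; a
   stricter per-block peptide check would flag in-alphabet substitutions
   that cross block profiles, and deliberately is not the default.

Aggregation (`cooccurrence()`, `representation_counts()`,
`nonredundant_counts()`, `aa_frequencies()`, `nnk_frequencies()`) follows
the published figures: co-occurrence counts ordered adjacent block pairs in
reads with ≥ 2 blocks, with UNMATCHED units breaking adjacency (a corrupted
unit makes both flanking junctions unverifiable); representation evenness
searches all decade windows anchored at observed counts (2000–20,000 was a
reported instance, not a fixed threshold); the poly-NNK reference is exact
enumeration of the 32 NNK codons — one stop (TAG), twenty residues.

## Numerical and degenerate-input choices

* Occupancy uses `expm1`/`log1p` exclusively; `N = 0` gives 0, `K = 1`
  gives 1.
* Empty inserts (adjacent anchors) are legitimate extractions classified
  wrong_length, since 0 is not a positive multiple of 18.
* Ties among equal-cardinality codon covers break lexicographically;
  among codons within `build_block`, by expansion size then
  lexicographically.
* All randomness flows from a single integer seed per entry point; the
  ligation engine uses R's own RNG from C++.
* The FASTQ reader validates per record (sequence/quality length, `@`/`+`
  markers) and reports the offending line; gzip is detected by magic
  bytes, not extension.

## Problem sizes used in the tests

The shipped test-and-acceptance workloads are desk-scale choices: ligation
and decoding checks run at 1e5 products (8e5 blocks) for matrix-dimension
and conservation properties, 4–5e3 complete products for round-trip and
noise-oracle checks, and occupancy comparisons at `K ≤ 1e4`, `N ≤ 1e5`
with 10 Monte-Carlo replicates. These sizes put Monte-Carlo error well
below the asserted tolerances while keeping a full run in tens of seconds.

## Known limitations

* The synthetic catalog reproduces the published library's aggregate
  statistics, not its sequences; analyses that depend on the actual oligo
  table (e.g. which residues each specific block favors) are out of reach.
* The ligation model has no kinetics; concentrations enter only through
  molecule counts. Circular products and adapter dimers are excluded.
* Decoding is exact-match only: indels shift every downstream unit and
  typically classify the read wrong_length; there is no fuzzy or
  alignment-based rescue.
* Headline accuracy percentages of the real sequencing run (75.3 % correct
  etc.) depend on that run's error profile and cannot be recomputed from
  synthetic data; the package instead verifies the classification
  machinery by round trips and analytic noise oracles.
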