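---
title: "Exact planted (l,d) motif search by l-mer pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact planted (l,d) motif search by l-mer pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifpair)
```

## The model

The planted (l, d) motif search problem asks, for t DNA sequences of
length n and parameters 0 ≤ d < l < n, for every l-mer m such that each
sequence contains a window within Hamming distance d of m. It is the
standard combinatorial abstraction of transcription-factor binding-site
discovery: the motif is the unknown binding preference, the per-sequence
windows are its mutated occurrences. An *exact* solver must report all
such m — the difficulty is that for "weak" parameter combinations the
number of spurious motifs (words satisfying the definition by chance)
explodes.

A useful difficulty measure is the probability that two random l-mers lie
within distance k of each other,
$$p_k = \sum_{i=0}^{k} \binom{l}{i} \left(\tfrac{3}{4}\right)^i
        \left(\tfrac{1}{4}\right)^{l-i},$$
the Binomial(l, 3/4) CDF. Evaluated at k = 2d it ranks instances:
`neighborhood_probability(15, 8)` ≈ 0.057 for the classic weak instance
(15, 4), while (27, 9) at ≈ 0.214 is hard enough to defeat most exact
solvers.

## Why pairs

Two instances of the same motif differ by at most 2d, so any two
sequences must each hold a window within 2d of each other for every
motif. The central object is the *shared candidate set* of a pair of
l-mers,
$$M_d(x, x') = \{y : d_H(y,x) \le d \;\wedge\; d_H(y,x') \le d\},$$
the intersection of two radius-d Hamming balls. Its size is a function
of (l, d, h) alone, where h = d_H(x, x'), and it collapses as h grows:

```{r}
candidate_count_table(15, 4)
```

At h = 0 the intersection degenerates to the full radius-d ball
(`sum(choose(15, 0:4) * 3^(0:4))` = 123 841); at h = 2d it is tiny; past
2d it is empty. The search therefore prefers pairs at large h, and the
algorithm's three stages are organized around that:

1. **Selecting pairs.** For each distinct l-mer x of sequence 1, the
   *reference sequence* is chosen among sequences 2..t to minimize the
   summed candidate counts over its windows within 2d of x
   (`select_reference()`); ties break to the lowest index. This avoids
   pairing x against near-copies of itself, which would multiply the
   candidate volume by orders of magnitude.
2. **Filtering.** For each pair (x, x'), windows z of the remaining
   sequences are discarded when they provably cannot witness any member
   of $M_d(x, x')$: rule 1 discards when $d_H(z,x) > 2d$ or
   $d_H(z,x') > 2d$; rule 2 classifies the alignment of (x, x', z) by
   the counts $(p_{10}, p_{00})$ and discards when no admissible
   signature ⟨α, β⟩ of the pair satisfies
   $|p_{10}-\alpha| + |p_{00}-\beta| \le d$. The two rules are
   incomparable — each catches words the other misses — and both are
   *sound*: the test suite verifies on randomized cases that nothing
   discarded is ever within d of an enumerated candidate.
3. **Verification.** Each y in $M_d(x, x')$ is accepted iff every
   remaining sequence keeps a surviving window within d of y. Sequence 1
   and the reference need no check: x and x' are within d of y by
   construction. The suite nevertheless re-validates accepted motifs
   against *all* sequences rather than trusting the optimization.

### The mapping relation and the traversal

A candidate y relates to its pair through the signature
⟨α, β⟩ = ⟨|P10|, |P00|⟩, where P10 are positions with x = x' but y
differing, and P00 positions with x ≠ x' and y matching neither. Since
$d_H(y,x) + d_H(y,x') = 2\alpha + 2\beta + (h-\beta) \le 2d$, the
admissible set — `mapping_relation(l, d, h)` — is
$\{\langle\alpha,\beta\rangle : \alpha \le l-h,\; \beta \le h,\;
2\alpha+\beta+h \le 2d\}$. Signatures partition $M_d(x,x')$ into
disjoint subsets, so the set can be *traversed* rather than discovered:
starting from y = x', flip α matched positions to one of 3 non-x bases,
flip β mismatched positions to one of 2 bases differing from both, and
reset k of the remaining mismatched positions to x's base, with
$\max(0, \alpha+h-d) \le k \le \min(h-\beta, d-\alpha-\beta)$ keeping
both distances within d. Summing the choices gives the closed-form
count
$$|M_d(x,x')| = \sum_{\langle\alpha,\beta\rangle}
  \binom{l-h}{\alpha} 3^\alpha \binom{h}{\beta} 2^\beta
  \sum_k \binom{h-\beta}{k},$$
and `enumerate_candidates()` emits exactly that many words, each once,
in a fixed order: signatures lexicographically, position subsets and
substitution bases ascending, k ascending. No order is mathematically
privileged; fixing one makes runs reproducible. The formula and the
traversal are validated against each other and against exhaustive
$4^l$ enumeration in the tests — the package trusts the definitional
oracle wherever any secondary source disagrees.

### Distances

All l-mers are encoded 2 bits per base (A = 00, C = 01, G = 10, T = 11 —
any bijection works; this one is fixed for reproducibility), base i in
bits 2i..2i+1. A distance is the XOR of two codes followed by ⌈l/4⌉
lookups in a 256-entry table holding, per byte, the number of non-00
2-bit fields. Words whose length is not a multiple of 4 are padded with
zero bits, which XOR to 00 and contribute nothing. The table path is
asserted equal to naive character comparison on 10⁴ random pairs for
every l in 4..32.

## The simulator

`simulate_planted()` reproduces the standard benchmark protocol: a
uniform random motif of length l, t sequences of i.i.d. uniform
background of length n, one occurrence implanted per sequence at a
uniform position, overwriting the background. Defaults t = 20, n = 600
are the conventional problem scale. Two mutation modes exist because
the literature is split on the occurrence model: `"exactly_d"`
(default) mutates exactly d positions — the fixed-mutation benchmark
model, and the harder search problem — while `"at_most_d"` draws the
count uniformly from 0..d. Mutated positions are a uniform subset; each
mutated base becomes a uniformly chosen *different* base, so recorded
mutation counts equal realized Hamming distances.

Determinism: one RNG stream, seeded once, consumed in a documented
order (motif; then per sequence: background, mutation count, positions,
replacement bases, implant offset). Identical seeds give byte-identical
FASTA and manifests; the caller's RNG state is saved and restored.

What the simulator does *not* emulate: biased or Markovian background
composition, positional bias of binding sites, multiple or missing
occurrences per sequence, overlapping decoy motifs, and
reverse-strand occurrences. Passing tests on simulated data therefore
certify the combinatorial guarantees (exactness, soundness,
completeness) — not biological recall on real promoters, where
objective-function choice dominates accuracy.

## Scoring and evaluation

For ranking reported motifs, two objective functions are provided over
the alignment of per-sequence best instances (minimal distance,
leftmost on ties — `extract_instances()`):

- **Consensus score**: sum over columns of the majority base count;
  integer in [l·⌈t/4⌉, l·t], maximal iff all instances agree.
- **Relative entropy**: $\sum_{\text{cols}} \sum_b f_b \log_2(f_b/p_b)$
  in bits, with column frequencies $f$ from counts plus a pseudocount
  and background $p$. Defaults: pseudocount 0.25 per base per column (a
  conventional fractional prior that keeps the score finite for
  unanimous columns), background = whole-dataset base frequencies in
  `pair_search()`/`score_motifs()` (uniform available); logs base 2.
  These conventions are choices, not consequences of the model; both
  knobs are exposed.

Prediction accuracy against ground truth uses the nucleotide-level
correlation coefficient
$$nCC = \frac{nTP \cdot nTN - nFN \cdot nFP}
 {\sqrt{(nTP+nFN)(nTN+nFP)(nTP+nFP)(nTN+nFN)}} \in [-1, 1],$$
computed from per-position confusion counts of one predicted vs one
true window per sequence (`confusion_from_positions()`). A zero
denominator factor leaves nCC undefined; the package returns `NA` with
a warning rather than coercing to 0. The one-truth-window-per-sequence
convention matches manifest-driven evaluation on planted data; real
annotation sets with absent or multiple sites per sequence would need a
more general matcher, which is out of scope here.

## Numerical and engineering choices

- **Exact counting in doubles.** Candidate counts and binomials use
  IEEE doubles, which hold integers exactly below 2⁵³ — covering every
  (l, d) with l ≤ 26 and every count this package reports. Numeric
  l-mer codes are likewise exposed only for l ≤ 26; all other paths
  take strings at the R boundary and 64-bit codes internally, so
  searches run for l up to 32.
- **Duplicate work avoidance.** Identical l-mer strings in sequence 1
  (or among reference windows) are processed once; a per-run memo of
  accepted and rejected candidate codes skips re-verification across
  pairs. Both are safe because verification is a pure predicate of the
  candidate and the sequences: a rejection means some sequence beyond
  the pair's witnesses truly has no window within d (filtering being
  sound and the 2d pre-scan complete), independent of which pair raised
  the candidate.
- **Degenerate inputs.** h = 0 pairs flow through the same traversal
  (β and k forced to 0). Windows containing non-ACGT characters are
  skipped with a warning rather than aborting the run; lowercase input
  is uppercased on read. Sequences shorter than l, t < 2, and d ≥ l are
  rejected with explicit errors.
- **Ordering.** Reported motif sets are sorted lexicographically;
  instance tables follow input sequence order; the motif set is
  invariant under reordering of sequences 2..t (verified by test).
- **Forward strand only**; no IUPAC ambiguity codes, no
  reverse-complement-aware distance.

## Problem sizes in the test suite

The suite proves `pair_search()` ≡ `brute_force_search()` on 50+
randomized instances with l ≤ 8, d ≤ 2, t ≤ 5, n ≤ 50 — sizes where the
4^l oracle is exhaustive yet fast — and checks planted-motif recovery at
(11, 2), t = 20, n = 100 and (15, 4), t = 20, n = 200. These scales were
chosen so the whole suite completes in a couple of minutes; the engine
itself solves the full (15, 4), t = 20, n = 600 benchmark in well under
a second on commodity hardware, and weaker instances such as (13, 4) at
n = 600 in tens of seconds. Worst-case time remains exponential in the
candidate volume, as it must for an exact PMS solver: expect long runs
when $p_{2d}$ approaches 0.5, where the motif itself becomes
statistically meaningless.

## Known limitations

- Counts (not searches) above l = 26 would lose exactness in doubles;
  no arbitrary-precision fallback is provided.
- nCC evaluation assumes exactly one true site per sequence.
- No branch-and-bound inside the candidate traversal and no
  parallelism; both are natural extensions, as each l-mer of sequence 1
  is processed independently.
- Ranking objectives assume position independence within the motif;
  binding sites with strong positional interdependence may rank the
  true motif below spurious ones regardless of search exactness.
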