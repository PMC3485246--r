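# motifpair

Exact planted (l, d) DNA motif search, driven by pairs of l-mers.

## The problem

Transcription-factor binding sites are short, degenerate DNA words. The
planted (l, d) motif search (PMS) model formalizes their discovery: given
t sequences of length n over {A, C, G, T} and integers 0 ≤ d < l < n,
find every l-mer m (a *motif*) such that each sequence contains a window
differing from m in at most d positions (an *instance* of m). PMS is
NP-hard, and "weak" instances — where d is large relative to l, such as
(15, 4) or (27, 9) — defeat naive enumeration because spurious motifs
abound.

This package implements an exact pair-driven search. Its key objects:

- **M_d(x, x′)** — the *candidate motifs shared by* two l-mers x and x′:
  all words within Hamming distance d of both, i.e. the intersection of
  their radius-d Hamming balls. Only these can have both x and x′ as
  instances, and |M_d(x, x′)| collapses rapidly as d_H(x, x′) grows (for
  (15, 4): 123 841 candidates at distance 0, but only 70 at distance 8).
- **The mapping relation R(x, x′)** — the admissible signatures
  ⟨α, β⟩ = ⟨|P10|, |P00|⟩ classifying each candidate y by how it meets
  the pair: α ≤ l − h, β ≤ h and 2α + β + h ≤ 2d, where h = d_H(x, x′).
  The relation drives both a filtering rule and a deterministic,
  duplicate-free traversal of M_d(x, x′).

The search loops over the l-mers x of sequence 1; for each it selects
the *reference sequence* minimizing the summed candidate counts of its
pairs with x, forms pairs (x, x′) with the reference's windows within
2d of x, filters the remaining sequences' windows with two sound rules
(the 2d criterion, and the signature-distance criterion
min ⟨α,β⟩ |p10 − α| + |p00 − β| ≤ d), and verifies each traversed
candidate against the surviving windows. The result is exactly the
definitional motif set — the package ships a 4^l brute-force oracle and
the test suite proves equality on randomized instances.

All distances run on a 2-bit-per-base encoding: XOR of two codes, then
⌈l/4⌉ lookups into a 256-entry table counting non-00 2-bit fields.

## Worked example

```r
library(motifpair)

# a standard benchmark-scale planted dataset: t = 20, n = 600, (l, d) = (15, 4)
ds <- simulate_planted(l = 15, d = 4, t = 20, n = 600, seed = 42)
ds$motif
#> [1] "AAAACTCCATGTGTA"

fit <- pair_search(ds$sequences, l = 15, d = 4)
fit
#> Planted (15, 4) motif search: 20 sequence(s), 1 motif(s)
#> # A tibble: 1 × 4
#>   motif           max_distance consensus_score relative_entropy
#>   <chr>                  <int>           <int>            <dbl>
#> 1 AAAACTCCATGTGTA            4             220             11.6

glance(fit)
#> # A tibble: 1 × 7
#>       l     d     t n_min n_max n_motifs   p_2d
#>   <int> <int> <int> <int> <int>    <int>  <dbl>
#> 1    15     4    20   600   600        1 0.0566

head(motif_instances(fit), 3)
#> # A tibble: 3 × 5
#>   motif           id    position instance        distance
#>   <chr>           <chr>    <int> <chr>              <int>
#> 1 AAAACTCCATGTGTA seq1       300 AATAATGGATGTGTA        4
#> 2 AAAACTCCATGTGTA seq2       457 AAAACAGAATGTTTA        4
#> 3 AAAACTCCATGTGTA seq3        35 CAAACACCATGTTCA        4
```

The planted motif is recovered as the unique (15, 4) motif. Per motif the
fit reports the worst per-sequence instance distance (`max_distance`,
here exactly d = 4 since instances were planted with exactly d
mutations), the consensus score (sum over the 15 columns of the majority
base count across the 20 aligned best instances; 220 of the maximal
15 × 20 = 300) and the relative entropy of the instance alignment against
the dataset's base composition in bits. `p_2d` is the probability that
two random 15-mers lie within 2d = 8 — the instance-difficulty measure.
When several motifs are reported, `score_motifs()` ranks them by either
objective, and adds the nucleotide-level correlation coefficient (nCC)
when a ground-truth manifest is available.

## Command-line interface

A launcher script is installed at `exec/motifpair` inside the package
(`system.file("exec", "motifpair", package = "motifpair")`); it wraps
`mp_cli()`:

```sh
motifpair simulate -l 15 -d 4 -t 20 -n 600 --seed 1 \
    --fasta data.fasta --manifest truth.tsv
motifpair search  -l 15 -d 4 -i data.fasta -o motifs.tsv
motifpair score   -l 15 -d 4 -i data.fasta -m motifs.tsv -o ranked.tsv \
    --manifest truth.tsv
motifpair eval    --predictions pred.tsv --manifest truth.tsv -l 15 -n 600
```

File formats (all tab-separated with a header line):

- **manifest** — `id`, `position` (0-based implant offset), `instance`,
  `mutations`: the simulator's ground truth, one row per sequence.
- **motif report** — `motif`, `n_sequences`, `max_distance`,
  `consensus_score`, `relative_entropy`, then one `pos:distance` column
  per sequence giving the best instance.
- **predictions** (for `eval`) — `id`, `position`.

Exit codes: 0 success, 1 user error, 2 internal error. Progress and, at
`--verbose`, the per-distance candidate-count table go to standard error.

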