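---
title: "Inferring regulatory networks from change correlation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from change correlation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airnet)
```

## The model

`airnet` treats a gene's expression profile across samples not as a set of
levels to be correlated directly, but as a source of *changes*. Two genes in
a signaling relationship need not sit at similar absolute levels in any
sample — individuals are sampled at arbitrary points of their internal
dynamics — but when one moves, the other tends to move (with it, or against
it). The package therefore:

1. discretizes each gene's profile into `k` activation levels,
2. classifies the joint level change of every gene pair over every *pair of
   samples* into promoting / inhibiting / still / mixed votes,
3. summarizes the votes into a signed influence value `v ∈ [−1, 1]` per gene
   pair, and
4. prunes the complete graph weighted by `w = 1 − |v|` down to a sparse
   network.

Using all sample pairs rather than consecutive samples is the point: `m`
samples yield `choose(m, 2)` comparisons instead of `m − 1`, and no
time-series assumption is needed.

### Discretization

Each gene is clustered independently (its own profile is one 1-D dataset).
We use the exact dynamic-programming solution of 1-D k-means — in one
dimension the SSE-optimal clusters are contiguous runs of the sorted values,
so the global optimum is computable in polynomial time — rather than Lloyd
iteration with random restarts. This buys three properties that matter for a
voting method: determinism (no seed sensitivity), label monotonicity (a
higher raw value never gets a lower level), and tie safety (the partition is
computed over distinct values with multiplicity weights, so equal raw values
always share a label).

One consequence is worth documenting: the published 5-gene worked example of
this method contains one row (`G4`) whose printed k = 2 labeling is *not*
SSE-optimal — placing 0.310 in the high cluster gives total SSE 0.06689
versus 0.06729 for the printed split. Whatever local optimum the original
implementation's initialization landed in is unknowable, so `airnet` returns
the global optimum and the test suite checks that row against an exhaustive
contiguous-partition oracle instead of the printed cell.

`k` defaults to 2 (on/off), which is the regime the voting rules were
designed around. For `k > 2` the strict vote rule (changes equal in
magnitude and sign) becomes conservative; a `match = "sign"` relaxation
(signs only) is available.

### Votes and the influence value

For samples `a, b` and genes `x, y`, with level changes `Δx, Δy`:

| category    | condition        | meaning                      |
|-------------|------------------|------------------------------|
| `p_same`    | `Δx = Δy ≠ 0`    | joint move, promoting vote   |
| `n_opposed` | `Δx = −Δy ≠ 0`   | opposed move, inhibiting vote|
| `q_zero`    | `Δx = Δy = 0`    | both still, weak promoting   |
| `u_mixed`   | otherwise        | no vote                      |

The influence value is the net vote fraction

$$v_{xy} = \frac{p + q - n}{\text{total}}.$$

The closed forms of the original equations were not recoverable from the
source text, so this formula is reconstructed from the three vote-rule
captions, the prose ("one vote for positive correlation … since neither gene
changed"), and the worked example (40 supporting votes over 45 sample pairs
→ 0.88). Because the both-still reading is the least certain part of the
reconstruction, `include_zero_votes = FALSE` preserves the alternative
`v = (p − n)/total`. The default is on. Note a structural consequence of the
default: two constant genes get `v = 1`. With expression data discretized
per gene this is rare (k-means on any non-constant profile occupies ≥ 2
levels), but it is the main reason the flag exists.

Sample pairs can be enumerated unordered (`C(m,2)`, default) or ordered
(`m(m−1)`). The published counts use both conventions in different places;
the two provably give identical `v` (every vote category is invariant under
pair reversal — the tests assert this), so the choice only affects the
reported `total`.

### Graph pruning

Candidates are processed in decreasing `|v|` (increasing `w = 1 − |v|`).
The stated stop rule — halt when the *weight* falls below a threshold — is
internally inconsistent (low weight means high correlation, and the
published illustrations show higher thresholds giving sparser networks), so
the threshold is applied to `|v|`: stop at the first candidate with
`|v| < threshold`. Two modes are provided:

* `forest` — Kruskal proper: an edge joining two already-connected genes is
  skipped. Output is acyclic, ≤ n − 1 edges (this is the letter of the
  described algorithm, and the default).
* `threshold` — keep every edge with `|v| ≥ threshold`. Provided because
  the published network illustrations contain cycles, which a strict
  spanning forest cannot produce; whether those figures used forest or pure
  thresholding is not stated.

Ties in `|v|` are broken lexicographically by gene pair, making output
deterministic. Retained edges carry the signed `v`, not `w`.

### Evaluation

Predictions are ranked by decreasing `|v|` (lexicographic tie-break) and
scored against an undirected gold standard: AUROC via the mid-rank
Mann–Whitney statistic (trapezoidal averaging over tied blocks) and AUPR as
average precision down the ranking. Significance is empirical: `n_null`
uniformly random rankings of the same candidate set — equivalent to random
networks of the same size, but requiring no re-tallying — are scored, and

$$p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + n_{\text{null}}}$$

(the add-one estimator, so `p > 0` and the combined score
`−log10(AUROC_p · AUPR_p)/2` is always finite). The published workflow used
100,000 nulls; the package default is 10,000 (desk scale, standard error of
a mid-range p ≈ 0.005) and `n_null` is a parameter. Results for several
same-sized networks are pooled by averaging the p-values first and
recombining — the published score table is arithmetically consistent with
exactly that order of operations, which the test suite verifies on all
twelve printed (score, AUPR_p, AUROC_p) triples.

### Network comparison

Two networks are diffed by unordered edge key: shared edges annotated with
`delta = |v_A − v_B|`, exclusive edges partitioned by condition, and sign
flips (promote in one condition, inhibit in the other) flagged — presence /
absence and strength shifts are what generate condition-specific hypotheses.
`delta` uses `v`; for same-signed edges the value is identical whether
computed on `v` or on `w = 1 − |v|`.

## The simulator: what it does and does not emulate

`random_truth_network()` draws a uniform random signed graph;
`simulate_expression()` produces a steady-state perturbation study: one
wild-type sample plus one sample per gene perturbation. Parameters and
defaults:

| parameter | default | meaning |
|---|---|---|
| `coupling` | 0.8 | neighbor shift as a fraction of its baseline (strong, near-complete propagation) |
| `noise_sd` | 0.01 | Gaussian measurement noise sd; baselines are drawn in [0.25, 1], so ~1–4% relative noise |
| `sign_fraction` | 0.3 | probability an edge is inhibiting (repressing links are the minority in curated networks) |
| design | `null-mutant` | perturbed gene forced to 0; `knockdown` halves it; `replicates` gives noisy wild-type copies only |

Propagation is one-hop and additive: perturbing a gene shifts each direct
truth-neighbor by `±coupling ×` its own baseline (down for promoting edges,
up for inhibiting), plus noise, clipped at 0 to resemble intensities. This
deliberately does **not** reproduce an ODE kinetics simulator: no multi-hop
propagation, no feedback equilibria, no trajectory data. The artifact under
test is the inference method, and one-hop steady-state shifts create exactly
the change-correlation signal it detects. A green recovery test therefore
establishes that the pipeline finds one-hop perturbation signal under low
noise — not that it matches any published benchmark score, which would
require the original external benchmark distributions. Knockout columns are
also the generator's only signal source, so the `replicates` design is
usable as a negative control.

## Numerical choices

* The k-means DP compares costs with a `1e-12` slack and keeps the earlier
  split on ties → deterministic labels.
* Empirical p-value comparisons use a `1e-12` slack on `null ≥ observed` so
  float noise cannot flip a tie.
* Network files print the shortest decimal string that parses back to the
  identical double, so edge-list TSV round-trips are lossless.
* Degenerate inputs: fewer distinct values than `k` occupy fewer levels (no
  error); a gold standard with zero positives or zero negatives is an
  explicit scoring error; an all-zero tally total is an explicit error.

## Known limitations

* Networks are undirected; the method cannot orient edges.
* Strict vote matching discards partially-matching multi-level changes;
  use `match = "sign"` for `k > 2`.
* The `q_zero` vote inflates `v` for near-constant gene pairs (see above).
* Empirical p-values are granular at `1/(n_null + 1)`; very strong
  predictions saturate at the floor.
* The influence computation materializes genes × genes matrices per vote
  category (memory ~ `8·G²` bytes each); fine into the low tens of
  thousands of genes, but the sample-pair dimension is streamed, not the
  gene-pair dimension.
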