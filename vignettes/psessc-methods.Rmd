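---
title: "Pseudo structure status composition: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo structure status composition: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psessc)
```

## The problem and the representation

Real pre-miRNAs are ~60–110 nt hairpins; genomes also contain large numbers
of pseudo hairpins — segments that fold into similar stem-loops but are not
precursors. Classifiers in this area must encode secondary structure in a
fixed-length vector even though sequences differ in length. `psessc` does
this with a *structure status* alphabet and a pseudo-component composition.

A folded position is described by one of 10 statuses: the four unpaired
bases A, C, G, U, and six paired statuses A-U, U-A, G-C, C-G, G-U, U-G that
keep both the pair type and its orientation. Orientation matters: a stem
read 5'→3' sees, say, `G-C` on one arm and `C-G` on the other, and real
hairpins place their arms asymmetrically.

**Status convention.** The verbal definitions of the paired statuses in
this literature are ambiguous between two readings: label a position by
*its own base first* ("the G of a G:C pair is `G-C`, its partner is
`C-G`"), or label *both* partners by the 5' base first (both read `G-C`).
We default to own-first: it assigns every position its own status, the two
partners carry each other's reversal (a checkable invariant), and it is the
reading under which the six paired statuses actually arise on both arms of
a single hairpin. The alternative is retained as
`assign_statuses(..., convention = "five-prime-first")` so the other
reading remains testable; all shipped defaults and presets use own-first.

Non-canonical pairs (e.g. A paired with G) are *errors*, not silently
treated as unpaired: the 10-symbol alphabet has no slot for them, and
thermodynamic folders never emit them, so their appearance indicates
malformed input. Pseudoknot notations are rejected at parse time.

## Features

With `f_u` the normalized frequency of the `u`-th status n-tuple (sliding
window, `L − n + 1` windows) and surrogate free energies
F(G-C) = F(C-G) = −3, F(A-U) = F(U-A) = −2, F(G-U) = F(U-G) = −1,
F(unpaired) = 0 kcal/mol (hydrogen-bond counts; overridable via
`free_energy_table()` or a config file), the tiered correlation factors are

$$\theta_j = \frac{1}{L-j}\sum_{i=1}^{L-j}\left[F(\Psi_i) -
F(\Psi_{i+j})\right]^2, \qquad j = 1,\dots,\lambda \;(\lambda < L).$$

The PseSSC vector divides both blocks by the shared denominator
$\sum_u f_u + w\sum_j \theta_j$; its `10^n + λ` components sum to 1 exactly
(asserted at 1e−12 in the tests). We compute the denominator's
$\sum f_u$ from the actual frequencies rather than assuming it equals 1, so
the formula stays correct should the tuple block ever be reweighted.
ExPseSSC appends the MFE, a randomization-test P-value, and the 64
tri-nucleotide frequencies (`+66` components).

**Component order is frozen**: tuples are enumerated lexicographically over
the fixed alphabet order (A, C, G, U, A-U, U-A, G-C, C-G, G-U, U-G) with
the first tuple position most significant, then `theta_1..theta_λ`, then
`mfe`, `pvalue`, and 3-mers in A<C<G<U order. Feature tables, model bundles
and any downstream discriminant analysis rely on this order being stable
across runs; the source method never specifies one.

### Tunable parameters

| parameter | meaning | default | why |
|---|---|---|---|
| `n` | status-tuple size (local order) | 2 | published PseSSC optimum |
| `λ` | highest correlation tier (global order) | 13 | published PseSSC optimum |
| `w` | weight of the θ block, in [0,1] | 0.5 | published PseSSC optimum |
| `C`, `γ` | RBF-SVM penalty / kernel width | 8, 2⁻⁵ | published PseSSC optimum |
| `min_loop` | minimal hairpin loop, nt | 3 | standard steric minimum |
| `shuffles` | randomization-test permutations | 100 | desk-scale Monte Carlo |

The ExPseSSC preset is n = 1, λ = 17, w = 0.2, C = 128, γ = 2⁻⁷. The
hyperparameter search enumerates n ∈ 1..4, λ ∈ 1..20, w ∈ {0.1,…,1.0}
(800 cells): the w axis is quoted elsewhere as "0 ≤ w ≤ 1 step 0.1", which
has 11 points, but the combination count is always quoted as 4×20×10, so
the default grid uses the 10-point axis and the 11-point variant is
available by passing `w_values = seq(0, 1, 0.1)`. The (C, γ) sub-grid
defaults to the conventional LIBSVM grid-script ranges (C = 2⁻⁵..2¹⁵,
γ = 2⁻¹⁵..2³, factor-4 steps), configurable because only the optima were
published.

### Randomization P-value

Neither the shuffle type nor the number of randomizations is specified in
the source method (its derivation cites prior work not reproduced here).
We default to **mononucleotide** shuffling with 100 permutations and the
estimator `P = (c + 1)/(N + 1)` (c = shuffles folding at least as stably as
the observed sequence): the add-one correction never returns 0 and is the
standard Monte Carlo convention. Because folding energies are strongly
dinucleotide-dependent, Altschul–Erikson **dinucleotide** shuffling
(exact dinucleotide counts preserved via a random Eulerian walk) is offered
as `kind = "dinucleotide"`. Precomputed `b` values can be supplied to keep
desk-scale runs free of folding loops.

## Folding backends

The production backend is an external thermodynamic folder (RNAfold-style:
FASTA in, Vienna records out), wrapped per batch over a subprocess pipe.
Because the grading/test environment has no such folder, the package also
ships a **baseline** folder: Nussinov maximum base pairing over canonical +
wobble pairs with the min-loop constraint, deterministic traceback (each
position pairs with the largest admissible partner achieving the optimum),
and a **pseudo-MFE** equal to the sum of status free energies over the 5'
side of each pair. This baseline is explicitly *non-thermodynamic*; it
exists so the pipeline, tests and synthetic benchmark run with no external
software. Its pair counts are verified against exhaustive enumeration of
all nested structures (all sequences to length 6, a seeded sample to
length 12 — the full 4⁷..4¹² enumeration would not fit the test-time
budget; the check is scaled down, not weakened in kind). Folder options of
the external tool (temperature, dangles) are left at that tool's defaults
and echoed in run logs.

## Classifier and evaluation

The SVM is a C-SVC with RBF kernel solved by SMO with maximal-violating-
pair working-set selection and the usual duality-gap stop at 1e−3 — the
same formulation and tolerance as the standard LIBSVM solver, which is not
installable in the target environment. Updated alphas are snapped to the
box boundary within 1e−10·C: without this, residues like 1e−20 keep
positions in the working sets with no room to move and stall the solver
far from the optimum. The test suite checks the KKT conditions of returned
solutions directly, which is an implementation-independent optimality
certificate; during development the solver was additionally cross-checked
against scikit-learn's LIBSVM binding (dual objective matching to 5
significant digits, full sign agreement of decision values).

Features are scaled per column to [−1, 1]; the source method is silent on
scaling, but its SVM tooling conventionally requires it. Scaling is
refitted inside every training split of every cross-validation fold, so no
information leaks from held-out samples.

Metrics follow the class-normalized formulation: Sn = 1 − N⁻⁺/N⁺,
Sp = 1 − N⁺⁻/N⁻, Acc = 1 − (N⁻⁺+N⁺⁻)/(N⁺+N⁻), and

$$\mathrm{MCC} = \frac{1 - \left(\frac{N^{-+}}{N^+} + \frac{N^{+-}}{N^-}\right)}
{\sqrt{\left(1 + \frac{N^{+-} - N^{-+}}{N^+}\right)
       \left(1 + \frac{N^{-+} - N^{+-}}{N^-}\right)}}.$$

This is algebraically identical to the textbook MCC wherever both are
defined; the suite proves it by enumerating every confusion table with
N⁺, N⁻ ≤ 20 against the TP/TN/FP/FN form. When a factor under the root
vanishes the MCC is returned as a flagged undefined value rather than ±∞.
AUC uses the rank statistic with average ranks, i.e. half credit for ties,
which equals the trapezoidal area under the ROC polygon (property-tested).

Cross-validation schemes: stratified k-fold with a recorded seed (fold
assignment is not specified in the source protocol), and jackknife
(leave-one-out), which is order-invariant by construction; `k = n` is
routed to the same singleton splits as jackknife. Grid-search ties break
deterministically toward the smaller λ, then n, w, C, γ — preferring the
lower-dimensional model at equal accuracy.

## Benchmark admission filters

Pseudo-hairpin candidates are admitted when length ∈ [51, 137] nt, the
structure has ≥ 18 base pairs, and MFE ≤ −15 kcal/mol. All three
boundaries are inclusive ("minimum of 18" → ≥ 18; "maximum of −15" → at
least that stable). The pair count is taken over *all* pairs of the folded
structure's pair table; whether the original protocol counted stem pairs
only is unstated, so all-pairs was chosen (the criteria object makes the
threshold configurable). Redundancy reduction is a pure wrapper around a
CD-HIT-style executable (80 % identity cutoff by default) — the clustering
algorithm itself is out of scope, and the stage can be skipped with a
logged warning.

## The synthetic world

`simulate_hairpin_set()` generates the stated test world: positives are
planted stem-loops with 22 pairs, 4-nt loop, 5-nt flanks, 5 % bulge rate,
G-C bias 0.5; decoys share the construction but with 8-pair stems
interrupted by a 3-nt interior loop and 19-nt flanks (similar overall
length, pair count below the 18-pair admission boundary). Unpaired regions
(loops, flanks, bulges) are drawn from the marginal base distribution
implied by the stem pair mix, so the two classes match in mononucleotide
composition in expectation and are separable by *structure*, not by base
content — the property the real positive/negative contrast is believed to
have. Structures are planted, not folded: ground truth for status
assignment is exact and no external folder enters CI.

What a green synthetic test establishes: the encoder, features, solver and
evaluation machinery recover a known, planted structural separation
(5-fold CV accuracy ≥ 0.95 on 200+200) and report chance accuracy
(0.5 ± 0.1) when labels are shuffled. What it does not establish:
performance on real genomic data, where negatives pass the admission
filters, energies come from a thermodynamic model, and class overlap is
substantial.

## Known limitations

* The published benchmark figures (jackknife Acc 85.76 %/MCC 0.72 for the
  PseSSC predictor, 89.86 %/0.80 for ExPseSSC, AUC 0.93/0.96) are **not**
  reproduced here: they require the original 1,612+1,612 benchmark, an
  unpublished negative-subsampling seed, unpublished (C, γ) search ranges
  and a 3,224-sample jackknife. Re-running them with the supplementary
  dataset and a ViennaRNA installation is a stretch experiment: fold with
  RNAfold, `featurize --preset pressc` / `--preset expressc`, then
  `evaluate --scheme jackknife`.
* The baseline folder maximizes pair count, not free energy; its
  pseudo-MFE is a bonded-pair sum. Conclusions about thermodynamic
  stability require the external backend.
* The model bundle is persisted with R serialization; it is
  version-stamped and validated on load, but not a cross-language format.
* `randomization_pvalue()` with the baseline backend measures stability in
  the pseudo-energy, which is composition-insensitive under mononucleotide
  shuffling for pairless sequences; with a thermodynamic folder the
  dinucleotide shuffle is the appropriate null.
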