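---
title: "Matrix completion over the tropical semiring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matrix completion over the tropical semiring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stmf)
```

## The model

Standard matrix factorization writes a data matrix as a product of two
low-rank factors under ordinary linear algebra, so every reconstructed entry
is a *sum* of latent contributions. This package replaces the arithmetic with
the tropical (max,+) semiring: the reals together with $-\infty$, with
$a \oplus b = \max(a, b)$ as addition and $a \otimes b = a + b$ as
multiplication. A rank-$r$ tropical factorization of an $m \times n$ matrix
$R$ is

$$R \cong U \otimes V, \qquad
(U \otimes V)_{ij} = \max_{1 \le k \le r} \left( U_{ik} + V_{kj} \right),$$

with $U \in \mathbb{R}^{m \times r}$ and $V \in \mathbb{R}^{r \times n}$.
Each entry is explained by its single *dominant* latent component rather
than by a blend of all of them. For expression data this is the right model
when one strong program drives an observation — the reconstruction tracks
extreme values instead of regressing toward the mean, which is where
ordinary non-negative matrix factorization (NMF) visibly fails on data with
a genuine (max,+) structure.

The fitting objective is the `b-norm` of the residual,
$\lVert R - U \otimes V \rVert_b = \sum_{(i,j)\ \text{given}} |R_{ij} - (U
\otimes V)_{ij}|$, summed over the *observed* entries only: missing entries
have no defined residual — they are the prediction targets of the matrix
completion.

## Solving one-sided tropical systems

Everything rests on one exact primitive. For the system
$A \otimes x \preceq c$ (the tropical order $\preceq$ is the entrywise
$\le$), the set of subsolutions always has a greatest element,

$$x_i = \min_{1 \le j \le m} \left( c_j - A_{ji} \right),$$

and when $A \otimes x = c$ is solvable at all, this vector attains it
exactly. Column-wise application gives `solve_right()` (the greatest $V$
with $U \otimes V \preceq R$) and `solve_left()` (its mirror for
$Y \otimes V = R$). With missing data the minimum simply skips unknown
entries — the masked (min,+) product `min_plus_masked()` — so each solver
needs a given entry in every column (respectively row) it reduces over, and
the fitted matrix must satisfy both, which `masked_matrix()` enforces.

Because subtraction appears in the formula, the $-\infty$ sentinel admitted
by the core algebra (`trop_add()`, `trop_mul()`, `trop_identity()`) is
rejected everywhere in factorization inputs and outputs.

## The fitting algorithm

`stmf()` proceeds as follows.

1. **Column ordering.** Columns are permuted so a per-column statistic over
   the given entries is non-decreasing (`column_min_increasing` by default).
   The per-entry updates visit entries in matrix order, so the visiting
   order matters; sorting columns by their minima was the most reliable
   strategy in our synthetic experiments, and the permutation is stored and
   inverted by `predict()`.
2. **Initialization.** Random Acol builds each column of $U$ as the
   entrywise average, over given entries, of `acol_subset_size` randomly
   sampled data columns (default $\lceil n/5 \rceil$, the usual convention
   for this initialization family). Averages of data columns start the
   factors at the data's own scale; rows with no given entry in a sampled
   subset fall back to the row's overall observed mean. A plain
   Uniform(0, 1) initialization is available for comparison.
3. **Initial solve.** $V$ is the greatest subsolution of
   $U \otimes X = R$; from here on the reconstruction is always tropically
   below $R$ at the given entries, so all residuals are non-negative.
4. **Sweeps.** Up to `max_iter` sweeps visit the given entries $(i, j)$ in
   row-major order. At each entry, the *active* index
   $k^* = \arg\max_k (U_{ik} + V_{kj})$ (smallest index on ties, for
   determinism) identifies the term realizing the reconstruction. The
   left-factor update (ULF) sets $U_{ik^*} \leftarrow R_{ij} - V_{k^*j}$ so
   the reconstruction can attain $R_{ij}$, then recomputes all of $V$ as
   the greatest subsolution; the right-factor update (URF) mirrors this
   through $V_{k^*j}$ and `solve_left()`. ULF is attempted first and URF
   only if ULF did not improve (`update_order` swaps them; on the synthetic
   regime the choice does not change fit quality, which the test suite
   checks statistically over seeds).
5. **Acceptance.** A candidate pair is accepted only when the training
   b-norm strictly decreases by more than `improvement_tolerance`
   (default 0, compared exactly: every candidate value is built from
   subtractions of representable input values, so exact repeats are
   representable and the comparison is safe). This acceptance rule is what
   *guarantees* the recorded error trace is non-increasing — the
   monotonicity is enforced, not hoped for.
6. **Stopping.** Fitting stops at `max_iter` sweeps or after the first
   sweep that accepts no update; under the acceptance rule such a sweep
   proves no single-entry update can improve further. The default budget of
   500 sweeps is far more than the synthetic regime needs (convergence is
   typically reached within a handful of sweeps); it is a safety ceiling,
   not a tuned constant.

`latent_component()` exposes the rank-one pieces
$R^{(i)} = U_{\cdot i} \otimes V_{i \cdot}$ (every entry a single sum); the
entrywise maximum of all components reproduces `predict()` exactly, which
the tests assert as an identity, not within a tolerance.

## What the synthetic generator does and does not emulate

`generate_tropical_lowrank()` draws $U$ and $V$ with i.i.d. Uniform(0, 1)
entries and returns $R = U \otimes V$, so every entry lies in $[0, 2)$ and
$R$ is *exactly* tropical low-rank: the attainability tests (`solve_right`
from the true $U$ leaves a zero residual) are exact statements about this
construction. `apply_mask()` hides `round(fraction * m * n)` entries —
uniformly at random by default (the protocol used throughout validation:
20% hidden, the rest training), or as a contiguous block
(`structured_block`) to stress not-missing-at-random patterns. Masks that
would empty a row or column are redrawn, up to 100 attempts. The held-out
true values are returned in a separate structure, never inside the training
object, so leakage into the fit is structurally impossible.

Two honest caveats about what passing tests on this generator demonstrate.
First, the generated matrices contain *no noise*: they are exactly
attainable, so near-zero training error is expected, and test error measures
pure structure recovery. Second, real expression matrices are not exactly
tropical low-rank; performance there depends on how dominant the strongest
latent program is. The synthetic results show the method identifies (max,+)
structure when it exists and that NMF cannot — they do not quantify real-data
accuracy.

## Evaluation statistics

`distance_correlation()` implements the distance-correlation association
measure: pairwise Euclidean distance matrices of the rows of $X$ and $Y$
are double-centered (`double_center()`: subtract row and column means, add
the grand mean), the squared distance covariance is
$V^2_{XY} = \frac{1}{n^2} \sum_{ij} A_{ij} B_{ij}$, and
$\mathrm{dcor} = \sqrt{V^2_{XY} / (V_X V_Y)}$ with
$V_X = \sqrt{V^2_{XX}}$. Unlike Pearson or Spearman correlation it detects
non-linear association; the population value is 0 only under independence.
Degenerate inputs (zero distance variance) return 0 by definition, and the
ratio is clamped to $[0, 1]$ against floating-point excursions. Note the
*sample* estimator is positively biased at finite $n$, and the bias grows
with the number of columns: for $n = 500$ independent rows it sits around
0.05–0.09 for univariate samples but around 0.14 for 3-column samples. The
package's independence checks therefore use univariate samples.

Model evaluation (`evaluate_completion()`) computes dcor between the full
original and reconstructed matrices — the mask-restricted RMSE
(`rmse_masked()`) carries the pure held-out signal — plus per-row Euclidean
errors (`centered_row_errors()`), optionally after column-mean centering of
each matrix (gene-wise centering for expression data, where dcor itself
cannot compare individual rows).

`compare_methods()` runs the full protocol against a classical NMF baseline
at equal rank: per repetition it draws a fresh mask and initialization from
a derived seed, fits both methods, and reports per-repetition train RMSE,
test RMSE and dcor with median/min/max summaries. The baseline is the
package's own implementation of the multiplicative-update NMF under the
Frobenius objective; since classical NMF has no native missing-data
handling, masked entries are column-mean imputed before the baseline fit (a
documented harness convention — it favors neither method on this data).

## Numerical and design choices

* Ties in max/min reductions take the smallest index; sweeps are row-major:
  fits are bit-for-bit reproducible given a seed, which the tests check by
  re-execution.
* Comparison tolerances in tests: exact (`identical`) where the arithmetic
  is exact (integer algebra, latent recombination, determinism), absolute
  `1e-9` for "attains zero" assertions on sums of doubles.
* Delimited output formats doubles with 17 significant digits and model
  containers use the same precision in JSON, so write/read round trips are
  exact; masked entries serialize as the empty string (with `NA`/`NaN`
  accepted on input).
* Validation problem sizes: the package's own test suite runs the regime at
  50 × 30 with rank 3, 10–20 seeded repetitions and a 100-sweep budget —
  small enough to run everywhere, large enough that the STMF-vs-NMF
  separation is unambiguous (median dcor ≈ 1.00 vs ≈ 0.99, median test
  RMSE roughly four times smaller for the tropical fit).

## Limitations

* No out-of-sample embedding: a new row or column requires refitting.
* Single data source; no multi-matrix fusion.
* Cost: every candidate update recomputes a full greatest subsolution, so a
  sweep is $O(|\Omega| \cdot mnr)$ for $|\Omega|$ given entries — orders of
  magnitude slower than an NMF update of the same size, the known price of
  the method. Rank selection is manual (fit candidate ranks, compare
  training error).

## A complete run

```{r example, eval = FALSE}
sim <- simulate_stmf_data(m = 100, n = 60, rank = 3, fraction = 0.2,
                          seed = 42)
fit <- stmf(sim$masked, rank = 3, max_iter = 100, seed = 42)
report <- evaluate_completion(sim$R, predict(fit), sim$test_mask)
report
nmf <- nmf_impute(sim$masked, rank = 3, seed = 42)
evaluate_completion(sim$R, nmf$WH, sim$test_mask)
```
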