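# stmf — sparse tropical matrix factorization

Low-rank matrix factorization and completion over the **tropical (max,+)
semiring**, for imputing missing entries in gene-expression and other sparse
real-valued data.

Ordinary factorization methods (NMF and relatives) model every entry as a
sum of latent contributions, which pulls predictions toward mean values and
blurs extremes. Over the tropical semiring — the reals with
`a ⊕ b = max(a, b)` and `a ⊗ b = a + b` — a rank-r factorization

    R ≅ U ⊗ V,   (U ⊗ V)_ij = max_k ( U_ik + V_kj )

explains each entry by its single dominant latent component, so sharp,
high-variance patterns survive reconstruction. The package fits `U` and `V`
to a partially observed `R` by minimizing the b-norm
`‖R − U ⊗ V‖_b = Σ_(i,j) observed |R_ij − (U⊗V)_ij|` with per-entry update
rules built on the exact *greatest subsolution* of one-sided max-plus
systems, `x_i = min_j (c_j − A_ji)`, extended to skip missing values via a
masked (min,+) product. Updates are accepted only when they strictly lower
the training error, so the fit descends monotonically by construction.

The package provides:

* the tropical matrix algebra (`trop_add`, `trop_mul`, `trop_leq`,
  `b_norm`, `greatest_subsolution`, `solve_right`/`solve_left`,
  `min_plus_masked`), with the hot solving loops compiled;
* the fitting algorithm (`stmf`) with Random Acol initialization, column
  ordering, a monotone error trace, `predict` for matrix completion and
  `latent_component` for rank-one reconstructions;
* a synthetic generator for tropical low-rank data with uniform or
  structured-block masking (`generate_tropical_lowrank`, `apply_mask`,
  `simulate_stmf_data`);
* evaluation statistics — distance correlation via double centering, masked
  RMSE, per-row centered Euclidean errors — and a comparison harness against
  a classical NMF baseline (`compare_methods`);
* delimited-matrix I/O with missing-value dialects, a JSON model container,
  and a CLI (`exec/stmf`: `simulate`, `fit`, `predict`, `evaluate`,
  `compare`).

## Worked example

Generate a 100 × 60 tropical rank-3 matrix, hide 20% of the entries, fit,
and compare against the NMF baseline:

```r
library(stmf)

sim <- simulate_stmf_data(m = 100, n = 60, rank = 3, fraction = 0.2, seed = 42)
fit <- stmf(sim$masked, rank = 3, max_iter = 100, seed = 42)
fit
#> stmf_model: 100 x 60, rank 3
#>   sweeps: 2, training b-norm: 50.74 (initial 1463.73)

evaluate_completion(sim$R, predict(fit), sim$test_mask)
#> dcor: 0.9985 | test RMSE: 0.0224 | train RMSE: 0.0214
#> row errors (centered): median 0.1092, max 0.2213

nmf <- nmf_impute(sim$masked, rank = 3, seed = 42)
evaluate_completion(sim$R, nmf$WH, sim$test_mask)
#> dcor: 0.9950 | test RMSE: 0.0927 | train RMSE: 0.0784
#> row errors (centered): median 0.5885, max 1.1333
```

The training b-norm drops from 1463.7 to 50.7 in a single sweep and the
fit stops when no single-entry update can improve it further. On data with
genuine (max,+) structure the tropical fit recovers the hidden entries with
roughly a quarter of the baseline's test RMSE and a higher distance
correlation — NMF's sum-based reconstruction cannot represent the max
structure and regresses toward means. `fit$error_trace` holds the
per-sweep objective (always non-increasing), and `latent_component(fit, i)`
shows which part of the data each latent component explains; their
entrywise maximum equals `predict(fit)` exactly.

The same pipeline from the shell:

```sh
Rscript exec/stmf simulate --m 100 --n 60 --rank 3 --mask-fraction 0.2 --seed 42 --out-prefix sim
Rscript exec/stmf fit --input sim_masked.csv --rank 3 --seed 42 --output model.json
Rscript exec/stmf predict --model model.json --output completed.csv
Rscript exec/stmf evaluate --truth sim_truth.csv --pred completed.csv --mask sim_mask.csv --output report.json
```

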