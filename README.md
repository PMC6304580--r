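# LaplacianMC

Dual Laplacian graph regularized matrix completion for drug–target
interaction (DTI) prediction.

Experimentally validated drug–target interactions are expensive to
establish, so the known interaction matrix of any benchmark is extremely
sparse (93–99.8% zeros on the classic nuclear receptor / GPCR / ion
channel / enzyme and DrugBank benchmarks). LaplacianMC ranks the
unobserved drug–target pairs by completing the binary interaction matrix
under a low-rank model that also exploits two side sources of
information: drug–drug chemical-structure similarity and target–target
genomic-sequence similarity. It is aimed at computational researchers who
have an interaction table plus similarity matrices (or raw fingerprints /
protein sequences) and want reproducible completion, ranking and
cross-validated evaluation.

## The model

Let `M ∈ {0,1}^{d×t}` be the interaction matrix, `A = M` its indicator
of observed interactions, `DS` (d×d) and `TS` (t×t) the two similarity
matrices, and `L_d = D_d − DS`, `L_t = D_t − TS` the unnormalized graph
Laplacians with degree matrices `D_d(i,i) = Σ_j DS(i,j)` and
`D_t(p,p) = Σ_q TS(p,q)`. The completed score matrix `X` minimizes

```
‖X‖* + α‖X‖²_F + β‖A∘X − A‖²_F + λ[ tr(XᵀL_d X) + tr(X L_t Xᵀ) ]
```

where `‖·‖*` is the nuclear norm (sum of singular values, the convex
surrogate for rank), `∘` the Hadamard product, and α, β, λ weight the
Tikhonov, observed-interaction fidelity and dual graph smoothness terms.
The smoothness term encodes that structurally similar drugs tend to
interact with similar targets, and sequence-similar targets with similar
drugs — it is the only conduit of information into fully blinded drugs
or targets (cold-start prediction).

The objective is solved by an inexact augmented Lagrange multiplier
(ALM) scheme on the split `X = J`, `X = Z`:

1. `J ← SVT(X + Y₁/μ₁, 1/μ₁)` — singular value thresholding, the
   proximal operator of the nuclear norm;
2. `Z_ij ← (2β A_ij + μ₂ X_ij + Y₂_ij)/(2β A_ij + μ₂)` — the fidelity
   system is diagonal, so the update is elementwise and exact;
3. `X` solves the Sylvester equation
   `[(2α + μ₁ + μ₂)I + 2λL_d] X + X [2λL_t] = μ₁J + μ₂Z − Y₁ − Y₂`,
   computed in the (cached) eigenbases of the two Laplacians;
4. multiplier ascent `Yₖ ← Yₖ + μₖ(X − ·)` with geometric penalty growth.

Predictions are the entries of `X` in descending order.

## Worked example

```r
library(LaplacianMC)

sim <- simulateDTI(seed = 1)   # 54 x 26, rank 3, ~93.6% sparse
ds  <- dtiData(sim)
datasetStats(ds)
#>   nDrugs nTargets nInteractions drugsPerTarget targetsPerDrug sparsity
#> 1     54       26            90           3.46           1.67    93.59

fit <- fitLapMC(ds)
fit
#> ALMFit: 54 x 26 scores, 95 iterations (converged)
#>   final residuals: |X-J| = 5.44e-07, |X-Z| = 7.74e-07
#>   final objective: 66.8539

predictTopK(fit, "D007", k = 5, excludeObserved = interactions(ds))
#>   rank targetId     score
#> 1    1     T004 0.3036097
#> 2    2     T017 0.3016013
#> 3    3     T007 0.3013988
#> 4    4     T011 0.2996385
#> 5    5     T024 0.2993288
```

`datasetStats` reports the conventional benchmark summaries: 90
interactions among 54×26 pairs is 93.59% sparsity, 3.46 interacting
drugs per target and 1.67 targets per drug. The fit converges when both
split residuals fall below 1e-6; the ranked targets for drug `D007`
exclude its training-observed interactions.

The ablation that motivates the graph term — identical cross-validation
with whole targets blinded, once with the smoothness weight on and once
with λ = 0:

```r
r <- recoveryExperiment(sim, seed = 1)
r$on   #> CVResult (targets): AUPR 0.217 +/- 0.000 over 1 repetitions
r$off  #> CVResult (targets): AUPR 0.122 +/- 0.000 over 1 repetitions
```

With the graph term the blinded-target AUPR roughly doubles; with λ = 0
a blinded column receives no information and the ranking is at chance
level (the positive prevalence here is 0.064).

A thin command-line interface wraps the same functions:

```sh
Rscript inst/scripts/lapmc simulate --out data --seed 1
Rscript inst/scripts/lapmc cv --interactions data/interactions.tsv \
    --drug-sim data/drug_sim.tsv --target-sim data/target_sim.tsv \
    --setting cv3 --folds 10 --reps 5 --seed 1 --out results
```

Every subcommand writes a JSON run report (resolved configuration,
input checksums, result summary) sufficient to replay the run.

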