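# vflsim — vertical federated learning with overcomplete autoencoders

`vflsim` is a single-machine simulation framework for a vertical federated
learning (VFL) protocol on clinical tabular data with a binary outcome. It
is aimed at methods researchers and biostatisticians who want to study —
before touching any governed data — how much predictive utility survives
when collaborating sites exchange *autoencoder latent codes* instead of raw
feature columns, and how far those codes actually sit from the raw data.

## The setting and the method

In vertically partitioned data, k sites hold disjoint feature-column blocks
X⁽⁰⁾, …, X⁽ᵏ⁻¹⁾ for the *same* individuals; only the binary target y is
held centrally. The simulated protocol is:

1. **Per-site encoding.** Site i trains an *overcomplete* autoencoder on
   its slice: categorical columns pass through learned embeddings
   (width min(50, ⌈cardinality/2⌉)), continuous columns are standardized,
   and fully connected ReLU layers 64–128–64 reconstruct the input, with
   squared error on continuous columns and softmax cross-entropy per
   categorical column. Overcompleteness means the code width m (128)
   is at least the post-embedding input width n, so information need not
   be lost while the feature space is transformed. Training is SGD with
   initial learning rate 0.01, per-epoch decay 0.99, and weight decay 0.1 —
   the stochasticity and the penalty are what keep the network away from
   the identity map h(x) = x that an overcomplete code invites.
2. **One-shot relay.** Each site transmits its code matrix Zᵢ = encᵢ(X⁽ⁱ⁾)
   once. A relay aligns rows across sites (sorted shared row IDs) and
   column-binds the codes into Z = [Z₀ | … | Z₍ₖ₋₁₎], width k·m.
3. **Central training.** A tabular neural network (embeddings for raw
   categorical inputs, hidden layers [200, 100], Adam) is trained on Z
   against y, and likewise on the raw pooled features and on each site's
   slice and codes as baselines.
4. **Evaluation.** All arms share one stratified held-out split; accuracy
   and AUROC (Mann–Whitney midrank form) are reported per arm, with signed
   relative percent differences 100·(after − before)/before.

Because no public clinical cohort ships with the package, a synthetic
generator provides mixed-type cohorts with a known, allocatable label
signal (class-shifted Gaussians, class-conditional multinomials) in three
preset shapes — 23,374×14 over 3 sites, 50×15 over 3 sites, 15,762×32 over
7 sites — so every claim the package makes is testable offline, including
against the closed-form Bayes accuracy of the generative family.

## Worked example

```r
library(vflsim)

spec <- syntheticPreset("adult_like", seed = 1)
spec@nRows <- 4000L                      # trimmed for a quick demonstration
ds   <- generateTabular(spec)
plan <- defaultPlan(spec)                # 3 sites, feature dims 5/5/4

report <- runBenchmark(ds, plan,
                       AutoencoderConfig(epochs = 20L),
                       ClassifierConfig(epochs = 10L),
                       seed = 1)
report
#> BenchmarkReport (accuracy / AUROC)
#>   central  before 0.84 / 0.91   after 0.77 / 0.83   diff -8.22% / -7.90%
#>   site_0   before 0.70 / 0.76   after 0.66 / 0.71   diff -5.21% / -6.92%
#>   site_1   before 0.74 / 0.81   after 0.66 / 0.74   diff -10.81% / -8.27%
#>   site_2   before 0.70 / 0.77   after 0.67 / 0.71   diff -4.46% / -8.54%
#>   (800 held-out rows; 24.6 s)
```

Reading the grid: the centralized raw-feature model reaches accuracy
0.84 / AUROC 0.91 on the held-out rows; after replacing every site's raw
columns by 128-dimensional latent codes and aggregating them (384 columns
total), the central model keeps 0.77 / 0.83 — a relative loss of 8.2% and
7.9% at this reduced cohort size and training schedule (the full-size,
full-schedule run lands near −7% for both; see below). Each `site_i` row
is the corresponding single-site baseline: alone, every site is far below
the central model both before and after encoding, which is the federation
argument — aggregation recovers most of what no site has by itself.

How far are the transmitted codes from the raw slice?

```r
parts <- verticalSplit(ds, plan)
ae    <- trainAutoencoder(parts[[1]], AutoencoderConfig(epochs = 20L), seed = 1)
assessPerturbation(parts[[1]], encodeLatent(ae, parts[[1]]))
#> PerturbationReport: feature space changed: TRUE; identity flag: FALSE
#>   max |r|(latent, original) = 0.9862
#>   ridge-probe R^2 (lambda = 1): median 0.987, max 0.988
#>   KS divergence: median 0.500
```

No latent column is a verbatim copy of an input column (identity flag
down) and the marginal distributions differ strongly (KS ≈ 0.5), but the
ridge probe shows the continuous columns remain largely *linearly
decodable* from the 128-dimensional code — the honest flip side of an
overcomplete representation that is built to lose no information. The
package reports this tension rather than hiding it; see the vignette
(`vignettes/latent-vertical-federation.Rmd`) for what these metrics do and
do not establish.

A thin command-line front end wraps the same functions
(`inst/cli/vflsim.R`): `synth`, `train-site`, `encode`, `aggregate`,
`train-central`, `evaluate`, `benchmark`, `privacy-check`, each with
explicit `--seed` flags.

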