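---
title: "Latent vertical federation: methods and design notes"
author: "vflsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent vertical federation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In vertically partitioned clinical data, several institutions hold
*different feature columns for the same individuals* — one hospital has the
laboratory panel, another the imaging-derived measurements, a third the
demographic record — and no one may pool raw columns centrally. Vertical
federated learning (VFL) aims to train a single classifier that uses all
columns without any site exposing its raw features.

`vflsim` simulates, on one machine, a particularly simple VFL protocol:

1. each site trains an **overcomplete autoencoder** on its own slice, an
   unsupervised step requiring no labels and no domain knowledge;
2. each site encodes its slice into a fixed-width **latent code** (one
   matrix, transmitted once — no iterative communication);
3. a trusted relay aligns rows across sites (row *i* at site A is row *i*
   at site B) and concatenates the code matrices column-wise;
4. a central server trains a tabular neural network on the aggregate,
   using the centrally held binary outcome.

The package's purpose is to benchmark this latent-federated model against
(a) the centralized model on raw pooled features and (b) per-site models,
and to quantify how far the transmitted codes sit from the raw features.

## The site autoencoder

Each site's network is a fully connected encoder/decoder with
rectified-linear hidden layers, default widths 64–128–64. The middle layer
is the **code layer** of width $m$; its post-activation output is what the
site transmits. Overcompleteness means $m \ge n$, where $n$ is the site's
input width *after categorical embedding*. A conventional bottleneck
($m < n$) must discard information; an overcomplete code can in principle
retain all of it while still re-representing the features, which is the
protocol's privacy mechanism: utility survives, the feature space does not.

Mixed column types are handled as in modern tabular deep learning:

* each categorical column gets a learned embedding of width
  $\min(50, \lceil \text{cardinality}/2 \rceil)$ by default (the rule is
  registered by name and swappable via `registerEmbeddingRule()`);
* continuous columns are median-imputed and standardized using statistics
  fitted on *training rows only*;
* the reconstruction loss is per-column: squared error on the standardized
  continuous columns plus softmax cross-entropy over each categorical
  column's original levels, summed, then averaged over rows. Cells that
  were missing in the input are excluded from the cross-entropy; a
  dedicated extra embedding row represents "missing" on the input side.

Training is plain SGD with initial learning rate 0.01, multiplied by 0.99
after every epoch, and weight decay 0.1 applied to weights and embedding
tables. The large weight decay together with stochastic updates is the
guard against the degenerate solution an overcomplete autoencoder invites —
learning the identity map, which would transmit the raw features in thin
disguise. The anti-identity outcome is testable: no latent column of a
trained model should be a near-exact linear copy of any standardized input
column (`assessPerturbation()` flags $|r| > 0.999$).

Choices the protocol leaves open, fixed here and recorded in configuration:

* **Epochs and batch size** default to 50 and 64. The decay is applied per
  epoch; a per-batch decay of 0.99 would collapse the learning rate within
  a single epoch at cohort sizes in the tens of thousands.
* **Code extraction** is post-activation (ReLU) output of the middle
  layer, so codes are nonnegative continuous values.
* **Initialization** is uniform fan-in scaling, seeded per site as
  `seed + siteIndex`: sites differ from one another, runs reproduce bit
  for bit.

## The central classifier

All benchmark arms share one `ClassifierConfig`: embeddings (same width
rule) for categorical inputs, hidden layers [200, 100] with ReLU, a single
sigmoid output, Adam (lr $10^{-3}$), 20 epochs, batch 128, decision
threshold 0.5 with ties called positive. Latent inputs are all-continuous,
so they bypass the embeddings and are simply standardized. Because every
arm uses the same architecture, optimizer and budget — only the input
differs — before/after comparisons isolate the effect of the latent
transformation rather than classifier tuning.

Metrics are accuracy at the threshold and AUROC in the Mann–Whitney
midrank form, $P(s_+ > s_-) + \tfrac12 P(\text{tie})$, which the tests pin
against a brute-force all-pairs oracle and an independent ROC
implementation.

## The benchmark protocol

`runBenchmark()` performs, per dataset and vertical plan:

* one stratified 80/20 train/test split, fixed *before* any site sees
  data and shared by every arm — otherwise before/after differences would
  confound split noise. The split protocol is this package's choice; per
  class, `round(class_n * 0.2)` rows are drawn to the test side.
* autoencoders are fitted on training rows only; test rows are only
  encoded. Fitting them on test rows would leak held-out information into
  the representation.
* arms: `central/before` (all raw features), `site_i/before` (one site's
  raw slice), `site_i/after` (that site's codes), `central/after` (the
  relay aggregate) — for $k$ sites, $2(k+1)$ evaluations on the identical
  held-out rows.
* reported differences are signed relative percents,
  $100(\text{after}-\text{before})/\text{before}$, rounded to 2 decimals
  for reporting; an accuracy move 0.83 → 0.82 is −1.20, not −1.00. Full
  precision is kept in the serialized report.

`sweepCodeDim()` repeats the federated arm across code widths with hidden
layers rescaled to $[m/2, m, m/2]$, skipping (with a warning) widths that
would violate overcompleteness at any site.

## Synthetic cohorts

No real cohort ships with the package; `syntheticPreset()` provides three
recipes whose *shapes* mirror the benchmark settings the protocol targets:

| preset | rows | columns | sites |
|---|---|---|---|
| `adult_like` | 23,374 | 8 categorical + 6 continuous | 5/5/4 |
| `schwannoma_like` | 50 | 1 categorical + 14 continuous | 7/3/5 |
| `eicu_like` | 15,762 | 12 categorical + 20 continuous | 3/4/9/3/3/4/6 |

The generative family is deliberately simple: balanced binary labels;
continuous columns Normal with a per-class mean shift $\delta$ (class 0 at
$-\delta/2$, class 1 at $+\delta/2$, common noise scale); categorical
columns drawn from class-conditional level probabilities (uniform for
class 0, a tilt of strength $s$ toward the first level for class 1). This
family was chosen because its Bayes-optimal accuracy has a closed form —
for continuous-only specs,
$\Phi\!\left(\lVert\mu_1-\mu_0\rVert / 2\sigma\right)$ — giving the tests
an analytic ceiling to check trained models against (the suite requires
recovery within 0.03 on a $\delta = 3$, two-feature fixture).

Preset effect sizes ($\delta = 0.6$, $s = 0.2$ for `adult_like`;
$\delta = 0.5$, $s = 0.3$ for `schwannoma_like`; $\delta = 0.4$,
$s = 0.15$ with 20% missing continuous cells for `eicu_like`) are fixed
recipe constants chosen once so that centralized accuracy lands in the low
0.8s — the utility regime the protocol is meant to operate in, where
retention is a meaningful question. `allocateSignal()` rescales per-column
effect sizes so chosen sites carry chosen shares of the total squared
effect, which reproduces the qualitative site-contrast phenomenology (a
signal-starved site underperforms alone and gains most from federation).

What the generator does *not* emulate: inter-feature correlation,
heavy-tailed or multimodal marginals, label noise, and missingness that is
informative rather than completely at random. Passing benchmarks on these
cohorts therefore demonstrate that the pipeline's machinery preserves a
recoverable signal through encoding and aggregation; they do not predict
retention percentages on any particular real cohort.

## Perturbation metrics

The protocol's privacy argument is qualitative (codes "look different").
`assessPerturbation()` makes it measurable with three package-defined
proxies: the maximum absolute Pearson correlation between any latent and
any standardized original column (with an identity flag at $|r| > 0.999$);
held-out $R^2$ of a closed-form ridge probe from codes back to each
continuous column (penalty 1 by default, reported, since attack strength
depends on it; the half-split alternates along row-ID order so the report
is invariant to common row permutations); and the two-sample
Kolmogorov–Smirnov statistic between each original column and its
best-correlated latent column. These are transparency metrics, not
guarantees: no differential-privacy accounting and no nonlinear inversion
attack is attempted, and what reconstruction level would constitute a
breach is a policy question the package does not answer.

## Numerical and scale choices

* All randomness flows through explicit integer seeds
  (`withr::with_seed`), making every stage — generation, balancing,
  splitting, training, encoding — a deterministic function of (input,
  seed).
* Degenerate inputs are handled explicitly: constant continuous columns
  standardize to zero (unit fallback scale); single-class labels raise
  errors rather than silent 0/1 metrics; a row count too small to
  stratify is an error.
* Divergence (non-finite epoch loss) aborts with the epoch number rather
  than propagating NaNs.
* Test problem sizes: most unit tests run on cohorts of 100–2,000 rows
  with small layer widths; the utility-retention checks run the full
  23,374-row `adult_like` cohort, three seeds at a shortened schedule
  (12 autoencoder epochs at batch 128, 8 classifier epochs at batch 256)
  plus one run at the full default schedule. These sizes are the package's
  own choice of test scale; the full default benchmark completes in a few
  minutes on a single CPU core.

## Known limitations

* The relay is an in-process function over matrices: no networking,
  cryptographic record linkage, or private set intersection; row
  identifiers are assumed already harmonized (rows missing at some site
  are dropped and counted, not imputed).
* Single split, no cross-validation; per-seed results are reported
  without inferential statistics across seeds.
* No denoising/variational/sparse autoencoder variants, no differential
  privacy, no homomorphic encryption — the protocol under study is the
  plain overcomplete-autoencoder exchange.
* Absolute benchmark numbers depend on the synthetic recipes; only
  within-run before/after contrasts are designed to be meaningful.
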