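---
title: "Measuring Notch pathway activity with a knowledge-based Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Notch pathway activity with a knowledge-based Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(notchscore)
```

## The model

`notchscore` treats pathway activity as a latent cause of target-gene
expression. A binary transcription-complex node TC (the NOTCH/RBPJ/MAML
complex: active or inactive) drives one latent transcription state per
direct target gene, G_g in {up, down}, and each gene state drives the
observed, discretized intensities of its probesets, O_j in {high, low}.
The joint distribution factorizes as

$$P(TC, G, O) = P(TC) \prod_g P(G_g \mid TC) \prod_{j \in g} P(O_j \mid G_g),$$

and scoring a sample computes the exact posterior log2-odds
$\log_2 \frac{P(TC=\mathrm{active}\mid O)}{P(TC=\mathrm{inactive}\mid O)}$
by marginalizing the gene layer analytically (a sum over two states per
gene). The log2 transform makes the scale symmetric around zero: a score
of 0 means the evidence is balanced, +1 means the observations are twice
as likely under an active complex.

The structure is *knowledge-based*: the 18 panel genes are curated
direct NOTCH targets, and the gene layer encodes literature-evidence
strength rather than anything fitted to the data at hand. Only the
observation layer is estimated, from a single labeled calibration
cohort, after which the model is frozen. This deliberately trades
flexibility for transferability across tissue types and guards against
overfitting — the classic weakness of purely data-driven signatures.

Assumptions worth keeping in mind:

* genes are conditionally independent given TC, and probesets given
  their gene — co-regulation beyond the pathway (shared chromatin state,
  copy number) is not modeled;
* evidence enters as hard high/low calls. Soft (continuous) evidence is
  a possible extension; with hard calls the score is a step function of
  each intensity at its threshold;
* all 18 genes are treated as up-regulated on activation. The data
  model carries a per-gene sign so other panels can reuse the machinery.

## Parameters and defaults

| parameter | default | units / range | rationale |
|---|---|---|---|
| `prior_active` | 0.5 | probability | makes the score a pure evidence measure |
| `gene_a` = P(G up \| TC active) | 0.95 | probability | strong literature evidence for the curated panel |
| `gene_b` = P(G up \| TC inactive) | 0.05 | probability | symmetric counterpart |
| `pseudocount` | 1.0 | counts | Laplace smoothing; keeps all CPT entries strictly inside (0,1), hence all scores finite |
| threshold `t_j` | calibrated | log2 intensity | midpoint of the class-conditional medians (`pooled_median` available) |
| `c_j`, `d_j` | calibrated | probability | smoothed per-class frequencies of high calls |

Numerical and convention choices:

* **Boundary:** an intensity exactly equal to `t_j` calls *low* — a
  deterministic tie-break, documented rather than delegated to floating
  point.
* **Ordering repair:** calibration can leave a probeset anti-correlated
  with the labels (`c_j <= d_j`). Such a probeset contradicts the
  knowledge-based direction assumption and is excluded from scoring by
  default (`anticorrelated = "invert"` swaps the pair instead).
* **Constant probesets** carry no class information; they fall back to
  a default mid-strength CPT (c = 0.75, d = 0.25) with a warning.
* **Log-space evaluation:** per-gene evidence factors are combined with
  a max-shifted log-sum-exp, so models with many probesets cannot
  underflow.
* **Freezing:** `freeze_model()` marks the model immutable; scoring is
  read-only, recalibration of a frozen model is refused, and
  serialization embeds an MD5 content hash that `read_model()` verifies.

`brute_force_posterior()` is a deliberately naive second implementation
— full enumeration of every (TC, G_1, ..., G_n) assignment — kept as an
oracle; the test suite holds the two routes together to 1e-9 on
randomized small models.

## Downstream clinical pipeline

* **Mutation strength.** Strong NOTCH1 activation = juxtamembrane-domain
  mutation, or heterodimerization-domain mutation combined with a
  PEST-domain or FBXW7 mutation; weak = any other single lesion among
  HD/PEST/FBXW7; none otherwise. The classifier is total over the 16
  flag combinations; unknown-status samples are excluded from
  mutation-based analyses only.
* **Activity groups.** Low < 25th percentile, high > 75th, middle
  otherwise; scores exactly at a cut go to middle, matching the strict
  inequalities of the grouping definition. Percentiles use R's default
  linear-interpolation quantiles (type 7): for 117 distinct scores this
  puts 29 patients in the low group, which is the group size the PTEN
  analysis relies on. Group assignment is invariant to monotone
  transformations of the score scale.
* **PTEN association.** The 2x2 table (low vs middle+high against PTEN
  loss) is tested with the Pearson chi-square *without* continuity
  correction: on the published counts (11/29 vs 12/84) the uncorrected
  statistic gives p = 0.006 while the Yates-corrected version gives
  p = 0.014, so the uncorrected form is the one consistent with the
  published analysis.
* **Wilcoxon.** Validation-style contrasts compare independent
  conditions, so `wilcoxon_two_condition()` defaults to the rank-sum
  test and offers the signed-rank variant for genuinely paired designs.
  Statistical correctness takes precedence over the test's historical
  naming in such comparisons.
* Missing clinical fields are dropped listwise per analysis and each
  result reports its own n, so the per-analysis cohort sizes vary just
  as they do in real annotation tables.

## The synthetic-data generator

The generator exists so that every pipeline stage is exercisable without
external data. It emulates:

* **Calibration cohorts:** two classes; per gene,
  `delta * 1[active] + N(0, sigma_gene)` on the log2 scale (defaults
  delta = 2, sigma_gene = 0.5); per probeset, a fixed baseline offset
  drawn uniformly from 6–10 log2 units plus `N(0, sigma_probeset)`
  (default 0.5). Additive Gaussian noise at both layers is the standard
  desk-scale approximation for log-intensity microarray data and keeps
  the calibration analytically checkable.
* **A T-ALL-style cohort** of 117 patients. Mutation classes are drawn
  at proportions 0.35/0.45/0.20 (none/weak/strong; the strong fraction
  follows the roughly one-in-five rate of the cohort the pipeline
  targets) and decomposed into domain flags that the classifier recovers
  exactly. Latent activity is the class shift (0/1.5/3 log2 units) plus
  N(0,1), with a +1 bump for the TLX subtype. ICN1 =
  5 + activity + N(0,1), truncated at zero (RPPA-style relative
  intensity units), measured for ~62/117 patients. PTEN loss is
  Bernoulli at 0.38 in the lowest latent-activity quartile vs 0.14
  elsewhere — the published loss rates — with ~4/117 missing. Mutation
  status is unknown for ~5/117.
* **Survival:** exponential event times (baseline hazard 0.08 per time
  unit over a 10-unit uniform censoring window, giving the ~35–45%
  event fraction typical of pediatric leukemia event-free survival) with
  the hazard multiplied for the lowest-activity quartile. The default
  multiplier is 5, chosen by an explicit power sweep (multipliers 3–6,
  40 replicates each): it is the smallest value at which the three-group
  log-rank test detects the constructed effect in essentially every
  replicate at n = 117, so a failed survival test signals a code defect
  rather than sampling noise.

Every generator takes an explicit seed, is bit-reproducible given it,
and restores the caller's RNG stream on exit.

What the generator does **not** emulate: full-transcriptome backgrounds,
array-level artifacts, batch effects, the correlation between molecular
subtype and mutation class (subtypes are sampled independently, with
only an activity bump for TLX), or correlated event/relapse processes
(the two endpoints are drawn independently). Passing tests on synthetic
cohorts therefore demonstrate that the machinery is correct under its
own model assumptions — not that the assay reproduces results on real
arrays, which additionally depend on platform preprocessing and a
vendor-calibrated frozen model.

## Scope and limitations

* The shipped HG-U133Plus2.0 probeset mapping is a provisional,
  editable stand-in (the authoritative per-gene probeset lists are not
  public); it is configuration data and all tests use synthetic probeset
  ids. Calibrated CPT values from the original assay are proprietary and
  are not reproduced.
* The contract starts at a normalized probeset-level matrix. Frozen-RMA
  preprocessing needs platform reference vectors and CEL files and is
  upstream of this package; `quantile_normalize()` (backed by limma) is
  a convenience for raw-ish log2 matrices. Quantile normalization is
  idempotent on tie-free data; with ties, tie-averaging makes a second
  pass differ slightly — an inherent property of tie handling, not a
  defect.
* `qc_flag()` implements four generic per-sample surrogates (median
  intensity, IQR, fraction missing, correlation to the cohort median
  profile), not the twelve vendor-recommended array QC parameters.
* Absolute score magnitudes scale with the number of informative
  probesets and the calibrated CPT strengths; scores are comparable
  within a frozen model, and ranks, groups and downstream statistics —
  not raw magnitudes — are the intended read-out.

## Problem sizes used by the test suite

Test cohorts are kept desk-scale: randomized oracle models up to 5 genes
x 3 probesets (100 replicates), calibration recovery at 200 samples per
class, separation checks at 50 per class, and single simulated clinical
cohorts of 117 patients; the chi-square power check uses 500 replicated
draws of the PTEN layer alone. These sizes give the properties under
test comfortable margins while the full suite runs in seconds.
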