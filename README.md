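# notchscore

Quantitative scoring of Notch signal transduction pathway activity from
gene expression, with the downstream clinical analyses used to interpret
those scores in T-cell acute lymphoblastic leukemia (T-ALL) cohorts.

Notch pathway activity cannot be read off reliably from NOTCH1/FBXW7
mutation status alone: samples without activating mutations can have an
active pathway and vice versa. `notchscore` instead infers *functional*
activity from the expression of 18 high-evidence direct NOTCH target
genes (CD44, DTX1, EPHB3, HES1, HES4, HES5, HES7, HEY1, HEY2, HEYL, MYC,
NFKB2, NOX1, NRARP, PBX1, PIN1, PLXND1, SOX9). It is aimed at
computational biologists working with probeset-level microarray-style
expression matrices who need a per-sample pathway read-out plus the
standard clinical follow-up analyses.

## The model

A three-layer Bayesian network with a latent binary transcription-complex
node TC (the NOTCH/RBPJ/MAML complex, active or inactive), latent
per-gene transcription states G_g (up/down), and observed probeset calls
O_j (high/low after thresholding normalized log2 intensities):

```
TC ──► G_1 ──► O_11, O_12, ...
  └──► G_2 ──► O_21, ...         P(TC=active) = 0.5 (prior)
  └──► ...                       P(G_g=up | TC), P(O_j=high | G_g)
```

Genes are conditionally independent given TC, probesets conditionally
independent given their gene, so the posterior odds factorize and are
computed exactly. The per-sample score is

```
score = log2 [ P(TC = active | O) / P(TC = inactive | O) ]
```

a symmetric log2-odds scale where 0 means no net evidence. The
gene-layer conditional probabilities encode literature evidence strength
(defaults a = 0.95, b = 0.05); the probeset layer (discretization
thresholds and P(high | up/down)) is calibrated on a labeled two-class
cohort — pathway-inactive normal tissue vs pathway-active tumor — with
Laplace smoothing, then **frozen**: scoring never mutates a frozen
model. A brute-force joint-enumeration oracle validates the exact
inference on small models.

Downstream, the package classifies NOTCH1/FBXW7 mutations into
none/weak/strong activation (strong = juxtamembrane-domain mutation, or
heterodimerization-domain mutation combined with PEST-domain or FBXW7
mutation), compares scores across groups (Kruskal-Wallis), correlates
scores with ICN1 protein levels, cuts cohorts at the 25th/75th score
percentiles, runs Kaplan-Meier/log-rank survival analysis, and tests the
low-activity group for enrichment of functional PTEN loss (Pearson
chi-square, no continuity correction). A synthetic-data module generates
calibration cohorts, on/off contrasts and a 117-patient T-ALL-style
clinical cohort so every stage is testable without external downloads.

## Worked example

```r
library(notchscore)

panel <- load_panel()                       # shipped 18-gene Notch panel

# calibrate on a simulated two-class cohort, freeze, then score an
# independent simulated T-ALL-style cohort
cal   <- simulate_calibration_cohort(calibration_cohort_spec(seed = 11), panel)
model <- freeze_model(calibrate(cal$expr, cal$labels, panel))
sim   <- simulate_tall_cohort(tall_cohort_spec(seed = 12), panel)
scores <- score_samples(model, sim$expr)
head(scores, 3)
#>   sample_id log2_odds n_probesets_used
#> 1   TALL001  43.36409               27
#> 2   TALL002  57.15196               27
#> 3   TALL003  49.04927               27

res <- analyze_cohort(scores, sim$clinical)
res$mutation_kruskal$medians
#>      none      weak    strong
#> -4.408520 26.922570 43.194162
res$mutation_kruskal$p_value     # 2.02e-10
res$efs_logrank$p_value          # 1.47e-13
```

Positive log2-odds mean the target-gene evidence favors an active
transcription complex; the score is a pure evidence measure under the
0.5 prior. In the simulated cohort, median scores rise from
mutation-free patients (−4.4) through weak (26.9) to strong (43.2)
NOTCH1-activating mutations, the groups differ significantly
(Kruskal-Wallis p ≈ 2e-10), and the lowest-score quartile has markedly
worse event-free survival (log-rank p ≈ 1e-13) — the qualitative
structure the assay is designed to expose.

The same pipeline is available from a shell via the thin front-end in
`inst/scripts/notchscore` (`simulate`, `calibrate`, `score`, `analyze`
subcommands; tab-delimited tables in, JSON reports out).

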