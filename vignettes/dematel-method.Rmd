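---
title: "The DEMATEL method in dematelr: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DEMATEL method in dematelr: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dematelr)
```

## The model

DEMATEL (Decision-Making Trial and Evaluation Laboratory) turns pairwise
expert judgments of directed influence into a structural map of a factor
system. Its input is a panel of $m$ experts, each scoring every ordered
pair of the $n$ factors on an integer scale from 0 (no influence) to 3
(very strong influence), with the diagonal fixed at zero: a factor is not
rated against itself.

The pipeline has four stages.

**1. Aggregation.** The direct-relation matrix $A$ is the unweighted
elementwise mean of the expert matrices,
$a_{ij} = \frac{1}{m}\sum_{k=1}^m a^k_{ij}$. We deliberately offer no
per-expert weights: the plain mean is the standard convention, and any
weighting scheme would need a justification the elicitation itself cannot
supply.

**2. Normalization.** $X = A / s$ with $s = \max_i \sum_j a_{ij}$, the
maximum *row* sum of $A$. Every entry of $X$ lies in $[0,1]$ and the row
attaining the maximum sums to exactly 1. Some presentations of the method
typeset the normalizing constant ambiguously between row and column sums;
we use the maximum row sum, the classical choice, and validate it by
reproducing the published tables of the packaged study end to end (see
below) rather than by assumption.

**3. Total relation.** $T = X(I - X)^{-1}$, which is the closed form of
the geometric series $X + X^2 + X^3 + \dots$: entry $t_{ij}$ accumulates
the direct influence of $i$ on $j$ plus all indirect influence routed
through chains of intermediaries. The series converges iff the spectral
radius of $X$ is below 1, which max-row-sum normalization guarantees
unless *every* row of $A$ attains the maximal sum (then $X$ is
row-stochastic and $I - X$ singular). That degenerate case is reported as
an error — `"non-convergent influence system"` — never silently
regularized, because any fudge factor would change every downstream
number in an uncontrolled way.

**4. Prominence and relation.** $R_i$ is the $i$-th row sum of $T$
(influence factor $i$ dispatches), $C_j$ the $j$-th column sum (influence
it receives). The sum $R + C$ ("prominence") measures total engagement in
the system; the difference $R - C$ ("relation") measures net role. A
factor with $R - C > 0$ belongs to the **cause group** (it drives the
system), otherwise to the **effect group**. Because influence is
conserved — $\sum_i R_i = \sum_j C_j = \sum_{ij} t_{ij}$ — the relations
always sum to zero: a system cannot consist of causes only.

For the causal network diagram, an edge $i \to j$ is drawn when $t_{ij}$
exceeds a threshold $\theta$, by convention the arithmetic mean of all
$n^2$ entries of $T$, **diagonal included**. Including the diagonal is a
real choice (the diagonal of $T$ is not zero even though the diagonal of
$A$ is); we verified on the packaged study that this convention, not the
off-diagonal mean, reproduces the published threshold.

## Tunable parameters

| Parameter | Where | Default | Meaning |
|---|---|---|---|
| `scale_max` | `expert_scores()` | 3 | Integer rating ceiling of the elicitation instrument. |
| `threshold` | `dematel()`, `build_network()` | mean of $T$ | Edge cut for the causal network; override to explore sparser/denser diagrams. |
| `edge_rule` | `dematel()`, `build_network()` | `"strict"` | `t_ij > θ` keeps an edge; `"inclusive"` uses `>=`. The boundary case is genuinely underdetermined by convention, so both are offered; the default treats values *at* the negligibility threshold as negligible. |
| `max_condition` | `total_relation()` | $10^{12}$ | Condition-estimate guard on $I - X$; above it the solve is refused. |
| `precision` | `write_analysis()`, CLI | full | Decimal places for display CSVs; JSON output always keeps full precision. |

Three further conventions are fixed rather than tunable, because they
affect comparability of results across runs:

* **Tie rule.** `classify_group(0)` returns `"Effect"` with a warning:
  cause membership is defined strictly by positivity, and a silent
  arbitrary choice on an exact tie would be invisible to the user.
* **Display rounding** is half away from zero (`round_half_away()`), not
  R's round-half-even, so printed tables are stable across platforms and
  match common spreadsheet conventions. All *comparisons* in the package
  and its tests are numeric on full-precision values; rounding happens
  only at the presentation boundary.
* **Self-loops** are never drawn in the network, even when $t_{ii} >
  \theta$: the diagram depicts inter-factor influence. The diagonal still
  participates in the threshold mean, as above.

## Numerical choices

$T$ is computed by a linear solve against $I - X$ (LAPACK, via
`solve()`), not by forming the explicit inverse; the reciprocal condition
number is estimated first and a system beyond `max_condition` is refused.
Entries of $T$ are mathematically non-negative (the series has
non-negative terms); round-off can produce values on the order of
$-10^{-16}$, which are clipped to zero, while anything materially
negative raises an error since it indicates an invalid input. The test
suite checks the fixed-point identity $T = X + XT$ to $10^{-9}$ and
agreement with an independently coded truncated-series oracle
($\sum_{k\le 200} X^k$) to $10^{-8}$ on random small systems.

## The packaged study fixture

The package ships, as plain CSV under `inst/extdata/`, the published
direct-relation matrix of a 15-motivator study of integrated-care
delivery by family physician teams: 15 factors (F1–F15) spanning
resident, team, institution, and government levels, averaged over a panel
of 20 experts and printed at 2 decimals. Four factor labels were not
available in transcribed form and ship as marked placeholders,
overridable via a user catalog file.

```{r}
res <- dematel(fpt_direct_relation())
res
```

The acceptance suite recomputes the full pipeline from this matrix and
compares against the study's published total-relation matrix (entrywise
within ±0.01 — the input is only printed to 2 decimals, so last-digit
drift is expected), its prominence/relation table (within ±0.02), its
exact 7-cause / 8-effect grouping, and its threshold 0.566 (±0.005).
Two remarks on fidelity:

* Several published matrix entries (e.g. 2.26) are not multiples of 1/20
  even though the panel had 20 experts, so the authors' unrounded inputs
  are unrecoverable; the fixture is the printed matrix as given, and
  `aggregate_panel()` supports any panel size.
* One published total-relation cell (F1, F5: 0.60) recomputes to 0.5947
  from the 2-decimal inputs and therefore *displays* as 0.59. This is the
  expected propagation of input rounding, not a pipeline discrepancy; all
  225 cells agree within the ±0.01 band.

## What the synthetic generator emulates — and what it does not

Raw per-expert questionnaires for the study are not available, so the
synthetic module generates panels with *known* ground truth to test the
pipeline by parameter recovery:

* `make_ground_truth()` draws base influences uniformly on $[0.5, 1.5]$ —
  the low band of the 0–3 scale, chosen so that a driver bonus has room
  to act before clamping — and adds a bonus $\delta > 0$ on every
  driver→non-driver cell for a designated driver subset. Drivers
  dispatch more than they receive, planting a known cause group.
* `simulate_panel()` models each expert's score as the latent influence
  plus independent Gaussian noise, rounded half away from zero and
  clamped to $\{0,\dots,3\}$ — the simplest distortion that produces
  legal integer ratings. Expert $k$ draws from substream `seed + k`, so
  panels of different sizes share their early experts and Monte-Carlo
  comparisons across $m$ are paired rather than independent.
* `recovery_experiment()` runs simulate → aggregate → analyze per
  replicate and reports the fraction of replicates recovering every
  planted driver in the cause group, plus the Spearman correlation
  between true and recovered prominence orderings.

```{r}
cat8 <- factor_catalog(paste0("F", 1:8))
recovery_experiment(cat8, drivers = c("F1", "F2"), delta = 1.5,
                    m_experts = 20, noise_sd = 0.5, replicates = 20,
                    seed = 11)
```

The validation conditions mirror the study's elicitation scale and panel
size ($m = 20$, scores 0–3): at $\delta = 1.5$, `noise_sd = 0.5`, $n =
8$, the suite requires driver recovery in at least 90% of 100 replicates,
and 100% in the noiseless case. Test problem sizes ($n \le 8$ for
simulations, $n \le 6$ for series oracles, 100 replicates) were chosen as
the smallest systems that still exercise every code path with stable
Monte-Carlo margins; the full suite runs in a few seconds.

What the generator does **not** model: correlated experts or bias
clusters, ordinal-logit response behavior, missing ratings, and
panel-specific reliability. A passing recovery experiment therefore shows
the *pipeline* is sound — aggregation is unbiased, grouping recovers
planted structure — not that any real panel's ratings are well
calibrated.

## Known limitations

* Cause/effect membership is a sign, not an inference: no uncertainty is
  attached to $R - C$, and a factor near zero (such as one with relation
  −0.07 in the packaged study) may flip under small input perturbations.
  The method itself offers no significance machinery, and we add none.
* "Key factor" selection beyond the ranked tables — combining prominence
  and relation into a single importance score — is left to the analyst.
  No consensus scoring function exists, so the package reports the
  components (`R`, `C`, prominence, relation, group) and the thresholded
  network from which such judgments are made by inspection.
* The labeled-matrix CSV dialect is deliberately minimal (UTF-8, `.`
  decimal separator, ids in the corner row/column); spreadsheet exports
  with locale decimal commas must be converted first.
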