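---
title: "Methods: from label-free serum proteomics to a verified biomarker panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from label-free serum proteomics to a verified biomarker panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seropanel implements a complete discovery-to-verification workflow for serum
biomarker studies built on label-free quantitative (LFQ) proteomics of a
matched case/control cohort, with targeted selected-reaction-monitoring (SRM)
follow-up. This vignette explains the statistical machinery, the choices the
package makes where the workflow leaves room, and what the synthetic-data
generators do and do not emulate.

## The discovery preprocessing chain

The discovery input is a MaxQuant-style protein-groups table: one row per
protein group with per-run normalized intensities. The chain applied by
`preprocess()` is fixed in this order:

1. **Identification filtering** — drop reversed-database decoys, groups only
   identified by a modification site, and groups supported by fewer than two
   unique + razor peptides. A row is a decoy if the reverse column is marked
   *or* any accession carries the decoy prefix; MaxQuant emits both signals.
2. **log2 transformation** of the raw intensities. Zeros were already
   converted to explicit missing values at parse time: a zero in this format
   means "not detected", and every downstream step depends on keeping that
   state distinct from a measured value.
3. **Valid-value filtering** — keep proteins measured in at least 50% of the
   analytical runs. The boundary is inclusive, and the fraction is computed
   over runs (not subjects) because filtering precedes replicate averaging.
4. **Imputation from a downshifted normal.** Serum LFQ missingness is
   largely left-censored: low-abundance measurements drop below the
   detection limit, so missingness is *not at random* (MNAR). Each missing
   cell in sample column $u$ is drawn from
   $\mathcal N(\mu_u - 1.8\,\sigma_u,\ (0.3\,\sigma_u)^2)$,
   where $\mu_u, \sigma_u$ are the mean and sd of the observed values of
   that column. The per-sample scope is the convention's common default; a
   global scope is available for sensitivity analysis. Draws are seeded.
5. **Replicate averaging** — quadruplicate runs are collapsed to one
   subject-level column by the arithmetic mean.

Averaging after imputation matters: imputing a subject-level average would
use a different censoring geometry. The orchestrator enforces the order; the
individual stages are exported for sensitivity runs.

## Differential abundance: reproducibility-optimized t-type statistics

Two-group comparison uses the statistic family

$$d_p = \frac{|\bar x_{1p} - \bar x_{2p}|}{\alpha_1 + \alpha_2 s_p},
\qquad s_p = \sqrt{s_{1p}^2/n_1 + s_{2p}^2/n_2},$$

which interpolates between the absolute mean difference
($\alpha = (1, 0)$) and the absolute Welch $t$ statistic ($\alpha = (0,1)$).
The regularization $(\alpha_1, \alpha_2)$ is not chosen by the analyst: it is
selected to maximize the *bootstrap reproducibility* of top-ranked protein
lists. For each candidate $\alpha$ and top-list size $K$, the package draws
pairs of group-stratified bootstrap data sets and measures the mean overlap
proportion $R_K(\alpha)$ of the two top-$K$ lists, and the same quantity
$R^0_K(\alpha)$ on group-label-permuted data; it then maximizes

$$Z_K(\alpha) = \frac{R_K(\alpha) - R^0_K(\alpha)}{\mathrm{sd}_{boot}\,R_K(\alpha)}.$$

When a candidate's lists are perfectly reproducible the bootstrap sd is
zero; the package scores these by the sign of the observed-minus-null gap
(an infinite $Z$), which keeps the selection well defined in strongly
separated data. If every candidate is degenerate the optimizer falls back to
the Welch corner with a warning.

Defaults: $\alpha_1 \in \{0, 0.01, 0.05, 0.1, 0.2, 0.5, 1, 2, 5\}$ with
$\alpha_2 = 1$, plus the $\alpha_2 = 0$ corner; $K \in \{25, 50, 100, 200\}$
capped at the protein count; 500 bootstrap pairs (overlap estimates
stabilize well below the permutation count; 1000 is available).

**Inference** is by group-label permutation (default 1000 permutations,
seeded). The p-value pools permuted statistics across proteins with an
add-one correction, $p = (1 + \#\{d^* \ge d\})/(1 + BP)$, so no p-value is
exactly zero and the resolution floor is explicit. The FDR is the
SAM-flavored per-permutation exceedance count divided by the observed rank,
median across permutations, clipped to $[0,1]$ and monotonized along
decreasing $d$. For tiny designs with fewer distinct label assignments than
requested permutations, all distinct assignments are enumerated instead
(and the p-values then agree exactly with exhaustive enumeration — this is
tested). The test is unpaired: pairing information is kept for the panel
stage's fold stratification, not used by the test itself.

Reported log2 fold changes are case-mean minus control-mean, so proteins
lower in cases carry negative values.

## Panel selection: stability Lasso + forward AUROC search

Discrimination is quantified by the AUROC in its Mann–Whitney form (the
probability that a random case outscores a random control, ties counted
one half), with variance, confidence intervals and paired model comparisons
from the DeLong placement-value (structural components) estimator —
implemented directly and cross-checked in the test suite against an
independent reference implementation and against a brute-force bootstrap.

Candidate discovery uses repeated cross-validated L1-penalized logistic
regression (`glmnet`): for each of 200 random 3-fold partitions — matched
pairs are never split across folds, which keeps every fold balanced — each
training portion is prescreened for differential abundance at $p < 0.05$,
an L1 path is fit on the standardized survivors, the penalty is chosen by
inner 5-fold cross-validated deviance, and proteins with nonzero
coefficients are counted. Selection frequency is selections divided by
(repeats × folds).

Two deliberate choices here:

* **Per-fold prescreening** (rather than reusing a global differential
  result) avoids selection-by-leakage; a global-reuse toggle exists for
  sensitivity analysis. The default prescreen statistic is a row-wise Welch
  test: refitting the full bootstrap-optimized permutation test inside
  every one of 600 training folds would multiply runtime by orders of
  magnitude while ranking proteins nearly identically at this step's only
  job (a 0.05 gate). The `diff_tester` argument accepts any function,
  including `rots_prescreen()`, when fidelity matters more than time.
* **Standardization and penalty choice happen inside training folds only**,
  so no test-fold information reaches the fit.

The final panel is built by a forward search over the 20 most frequent
candidates (ties broken by smaller differential p, then lexicographically):
starting from the top candidate, each step adds the candidate maximizing
the cross-validated AUROC of an unpenalized logistic model, scored by
leave-pair-out predicted probabilities (deterministic — no fold
randomness). The search stops at the first addition that does not
*improve* AUROC at DeLong $p < 0.05$; requiring an actual increase (not
just a small two-sided p) prevents a significantly *worse* addition from
extending the panel. Stopping at the first non-significant addition yields
the smallest panel among those whose every step is justified. Because the
candidate maximization inflates the nominal test level, the stop rule
leans on cross-validated scores: overfit additions usually *lower* CV
AUROC and terminate the search.

Both the cross-validated and the apparent (full-data fit) panel AUROC are
reported, clearly labeled, since published ROC figures frequently show the
apparent curve.

## SRM verification

Targeted verification quantifies each analyte against its spiked
heavy-isotope standard: the unit of analysis is
$\log_2(\text{light area}/\text{heavy area})$ per transition and sample.
The chain is: ratios → per-sample normalization by the median housekeeping
peptide ratio (complement C1s TNFDNDIALVR by default) → peptide
include-lists (the in-silico stand-in for manual interference curation;
fibulin-1C is restricted to DLLLTVK by default) → Tukey median polish of
each protein's transitions × samples grid (tolerance $10^{-6}$, 50 sweeps,
missing cells allowed) whose overall + column effect is the per-sample
protein summary → per-protein equal-variance linear model of summary on
group, giving the log2 case/control ratio, a Wald CI (99% by default) and a
two-sided p-value, Benjamini–Hochberg adjusted across the target family.
Housekeeping proteins and the apolipoprotein B-100 risk-factor control are
measured but excluded from the adjustment family. With one SRM run per
subject the full mixed-model summarization collapses to exactly this fixed
linear model, which is why the simpler model is used; BH is the package's
choice of adjustment where the convention leaves the method unstated.
Light rows without a usable heavy partner are dropped and counted, never
silently.

## What the synthetic generators emulate

`simulate_discovery()` reproduces the study geometry: 43 matched pairs in
quadruplicate (344 runs), ~300 protein groups, seven planted log2 effects
(−0.35, −0.32, −0.27, −0.19, −0.13, +0.22, +0.40 — the magnitudes reported
for the differentially abundant serum proteins), per-protein baselines
$\mathcal N(24, 2^2)$ on the log2 scale, biological sd 0.5, replicate sd
0.15, and probit MNAR missingness: a cell is observed with probability
$1 - \Phi((m - v)/s)$ with midpoint $m = 20$ and slope $s = 1$, giving a
few percent overall missingness concentrated in low-abundance proteins.
Decoy and single-peptide rows (5% each) are injected so identification
filters are exercised. Noise magnitudes are not published quantities; they
were fixed once at values giving realistic power at this design size and
are config-exposed.

`simulate_srm()` reproduces the targeted assay: 10 proteins, 23 proteotypic
peptides, 3 transitions each, one undepleted run per subject, heavy spike
with per-transition response factors, planted fibulin-1C case/control ratio
0.85 (all others 1), housekeeping at ratio 1 tracking a per-batch additive
drift (sd 0.2, two batches), subject sd 0.25 for analytes and 0.05 for the
housekeeping references (they are chosen for consistency, and their noise
propagates through normalization into every analyte), transition noise
sd 0.1.

`simulate_panel_benchmark()` constructs three *complementary* informative
proteins among 97 nulls by splitting cases into three latent subtypes, each
elevated by $\delta$ in exactly one panel protein — so each addition to the
panel contributes a disjoint slice of cases, the cleanest additive-logit
notion of complementarity and a plausible cartoon of proteoform/phenotype
heterogeneity. The elevation default $\delta = 4$ was fixed by a power
calibration before freezing the benchmark: at 43 pairs, $\delta = 3$ leaves
the third forward-search addition under-powered, and $\delta = 4$ is the
smallest scanned value at which every step-wise addition is well powered;
larger values add nothing. The test suite verifies trio recovery at the
frozen default.

What the generators do *not* emulate: peptide-level quantification and
protein inference, correlated protein modules, heavy-tailed and
batch-structured LFQ noise, depletion artifacts, interference in
transitions, or retention-time behavior. Green tests therefore demonstrate
that the machinery is correct and calibrated under the stated stochastic
model — not that real serum data meet that model.

## Numerical and reproducibility choices

* All stochastic stages take explicit seeds; the orchestrator derives
  per-stage child seeds from the run seed by a fixed hash, so stage
  outputs are reproducible independently of execution order. Reruns with
  the same configuration are byte-identical on disk.
* Permutation p-values use add-one correction; FDR values below the
  permutation resolution are written as `"<1e-04"` in result files (an FDR
  printed as 0 means below $10^{-4}$).
* Median polish: tolerance $10^{-6}$, max 50 sweeps, `na.rm` medians.
* Degenerate inputs have defined behavior: constant matrices give $d = 0$
  and $p = 1$; all-null panels return a graceful "no panel" result; zero
  heavy areas exclude a transition with a logged count; a sample column
  with fewer than two observed values is an imputation error naming the
  column.
* Statistic ties in ranking are broken "first" (stable) in the bootstrap
  overlap machinery and by max-rank in FDR denominators.

## Problem sizes used by the test suite

The acceptance-style tests run at the full design size where the check is
about the design (type-I error and fold-change recovery at 43 + 43, SRM
coverage over 100 seeds) and scale down only the resampling knobs that
do not change what is being measured: 100 bootstrap pairs for the null
calibration run, 50 stability repeats × 3 folds × 50 seeds for panel
recovery, 200,000 bootstrap replicates for the DeLong comparison. The
methods' full defaults (500 bootstrap pairs, 200 repeats, 1000
permutations) are exercised by `scripts/acceptance.R`.

## Known limitations

* The unpaired test ignores the matched design; pairing is honored in fold
  construction only. A paired variant is an explicit non-goal.
* The forward search's stopping test is performed on the maximizing
  candidate and is therefore anti-conservative as a pure significance
  statement; it is a model-selection heuristic, mitigated by CV scoring.
* BH adjustment across seven SRM targets is one defensible choice among
  several; the adjustment family and method are config-exposed.
* Imputation assumes the downshifted-normal model everywhere a value is
  missing; proteins missing for non-abundance reasons will be biased low.
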