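---
title: "Methods: differential methylation and prognosis across melanoma progression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation and prognosis across melanoma progression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylprog)
```

# Scope and data model

`methylprog` analyses DNA methylation beta values — per-CpG methylation
fractions in [0, 1] — measured on samples from three melanoma progression
groups: benign nevi, primary tumors, and metastases. The package starts
from a normalized beta matrix; raw-intensity preprocessing, normalization
and genome-build handling are deliberately upstream of it. Missingness is
carried as `NA` in the matrix and shared by all downstream statistics:
when a detection-p table accompanies the betas, calls with detection
p > 0.01 are masked at read time (`read_beta_matrix()`), so every stage
sees the same mask. Probe QC (`qc_filter_probes()`) removes genotyping
control probes and probes overlapping known SNPs; the SNP flag is taken
from the annotation rather than recomputed, because the defining variant
catalogue is a property of the input manifest, not of this package.

# The differential-methylation core

## ANOVA pre-screen and clustering

`anova_screen()` keeps a probe when a one-way ANOVA across the three
groups rejects at confidence 0.99 (p < 0.01) **and** at least one pair of
groups differs in group-median beta by ≥ 0.33. "A difference in at least
two groups" is read as "at least one pair of groups", the only reading
coherent with three groups and a single confidence level; a stricter
two-pairs reading is available via `min_pairs = 2`. The F statistic is
computed vectorised from the one-way sum-of-squares decomposition over
non-missing values — necessary at array scale — and the test suite pins it
to `stats::aov` on small cases. Probes with fewer than two non-missing
values in two groups, or no residual degrees of freedom, are skipped; a
probe with zero within-group variance but real between-group spread is
assigned p = 0 (the F statistic diverges), and a fully constant probe
p = 1.

`ward_cluster()` clusters samples with the Ward minimum-variance criterion
(`stats::hclust`, `ward.D2`, Euclidean distances). Missing betas are
mean-imputed per probe beforehand — imputation only affects distances, not
any test statistic. A probe that is entirely missing imputes to 0.5, the
uninformative midpoint. Tie-breaking in merge order is `hclust`'s
deterministic rule, so repeated runs agree.

## DGMB selection

`dgmb_compare()` implements the selection procedure in its stated order:
per probe, the difference of group methylation medians
(DGMB = median of the later stage minus median of the earlier stage) is
computed over non-missing values; probes with |DGMB| < 0.25 are discarded
*before* any testing; the surviving probes are tested with a two-sided
Mann–Whitney test; Benjamini–Hochberg adjustment runs within that gated
family, and significance requires adjusted p < 0.05. The gate-then-test
order matters: it fixes the multiplicity family to the large-effect probes.
The alternative (test and adjust everything, then gate) is available as
`gate_order = "test_then_gate"` since the effect on the BH family is a
genuine analytical choice.

A probe is testable only with ≥ 3 non-missing values per group
(`min_group_n`); untestable probes are excluded and their IDs kept in the
result's `untestable` attribute rather than silently dropped.

`mann_whitney()` uses the exact null distribution when the combined sample
size is ≤ 12 and the data are tie-free, and otherwise the normal
approximation with tie and continuity correction. Whether the original
analysis was exact or asymptotic is not documented anywhere authoritative;
both branches are provided and the dispatch is explicit (`mode`). The
exact branch is verified against full enumeration of group assignments in
the tests; the asymptotic branch is calibrated under the null (type-I
error at nominal 0.05 over 10^4 replicates of 30 vs 30).

## Crossing, compartments, reporting

Development (nevus → tumor) changes must be significant with a consistent
direction in both *nevus vs primary* and *nevus vs metastasis*; probes
significant in both but with conflicting directions are excluded and
logged, and probes significant in only one comparison are reported
separately (`dev_partial_probes`). Progression changes come from
*primary vs metastasis*. Gene-level sets use exploded, upper-cased
manifest symbols; a gene enters a hit list if at least one of its probes
is significant, and counts as a promoter gene if a significant probe sits
in TSS1500, TSS200, 5'UTR or 1stExon. These "at least one probe"
conventions are the permissive standard for array gene summaries; they
overcount genes relative to probe-majority rules, which is acceptable for
list-level reporting but should not be read as per-gene effect estimates.

Compartment profiling classifies probes by distance to the nearest CpG
island: island inside, shore within 2 kb of an edge, shelf 2–4 kb,
open sea beyond. The widths are the universal Illumina convention (the
category names alone do not define them). Coordinates are 1-based
inclusive, distances are absolute base-pair differences, and strand is
ignored. The island-association test is a two-tailed Fisher exact test on
{hyper, hypo} × {island, non-island}. All reported percentages recompute
as `round(100 * part / whole, 1)` from their own counts — never stored and
re-rounded.

# Expression integration

Expression tables arrive pre-computed (gene, log2 fold change, q); the
package never touches raw chips. A gene call is `down`/`up` when
|logFC| ≥ 1 (two-fold) and q < 0.05. "Negative correlation" between
methylation and expression is operationalized as direction-concordant
significance — hypermethylated & down, or hypomethylated & up, in at least
one table (OR semantics) — because methylation and expression cohorts are
in general disjoint, so no per-sample correlation exists to compute. Gene
matching is exact after upper-casing; alias resolution is out of scope and
a documented limitation. The gene-set step is a hypergeometric
overrepresentation test (`geneset_overlap()`): upper-tail P(X ≥ k) with BH
across sets, with set members outside the stated universe dropped and
counted. Ranked-list enrichment statistics are intentionally not
implemented; overlap counts are what the downstream reporting consumes.

# Prognosis

The survivor signature compares primary tumors from patients who died of
disease before 48 months with patients surviving beyond 48 months, probe
by probe, by group **means** (the DGMB screen uses medians; the signature
deliberately follows the mean-difference convention of survivor
comparisons), Mann–Whitney p, BH adjustment, and the selection rule
|Δmean| ≥ 0.2 with adjusted p < 0.01. Two patient categories are
ambiguous: survival exactly at the cutoff, and censored patients with
follow-up shorter than the cutoff. Both are excluded by default (standard
practice — they are neither short nor demonstrably long survivors); the
latter can be counted as long survivors via `short_followup_as_long =
TRUE`. Survival is melanoma-specific by construction of the sample sheet's
event flag.

Kaplan–Meier estimation, the log-rank test and Cox regression are
delegated to the `survival` package (`survfit`, `survdiff`, `coxph`) —
the field's reference implementation — behind thin validated interfaces,
and are pinned in the tests to hand product-limit computation, a hand O−E
table, and brute-force partial-likelihood maximization respectively. Cox
ties default to the Breslow approximation (whose likelihood is clean to
verify by brute force), with Efron behind `ties = "efron"`. Monotone
likelihoods (perfect separation) and constant covariates are reported as
`converged = FALSE` with `NA` estimates instead of spurious numbers; the
divergence heuristic is |coef| > 15 or SE > 100, far outside any plausible
hazard scale. Breslow thickness enters as a continuous covariate by
default; dichotomize it beforehand with `dichotomize()` to mirror
high/low-thickness grouping.

`dichotomize()` splits at the cohort median, first or third quartile
(type-7 linear-interpolation quantiles — stated because quantile
conventions differ across software), or a fixed cutoff; `high` is strictly
above the cutoff and ties go to `low`. The H-score
(`compute_hscore()`) is the canonical intensity-weighted percentage sum
`1·pct1 + 2·pct2 + 3·pct3` in [0, 300]; the upstream image analysis that
produces the intensity histogram is out of scope.

# The synthetic-data generator

The generator exists so that every stage has a recovery test with known
ground truth. Design choices, in the package's own judgment:

* **Noise model.** Beta distribution per probe, parameterised by mean and
  precision (`beta_precision`, default 50). A Beta law is the standard
  bounded model for methylation fractions; precision 50 gives
  within-group standard deviations around 0.05, typical of 450K probes.
* **Baselines.** Probe baseline means come from a bimodal mixture (Beta(3, 17)
  and Beta(17, 3), modes near 0.15 and 0.85, equal weight), mimicking the
  bimodal marginal distribution of real arrays and making both hyper- and
  hypomethylation plants feasible. Hyper plants are forced onto
  low-baseline probes (and vice versa) and clamped so the shifted mean
  stays inside (0, 1); effect sizes too large for any valid baseline are
  rejected.
* **Planted classes.** Development probes shift both tumor groups by
  `effect_delta` against nevi; progression probes shift only metastases;
  prognostic probes shift the high-risk half of primary tumors by
  `prognostic_delta`. The default `effect_delta` of 0.4 straddles the
  0.25 DGMB gate with realistic margin; `prognostic_delta` defaults
  to 0.3, the operating point of the survivor-signature recovery
  condition. The default cohort is 14 nevi / 33 primaries / 28 metastases,
  the discovery-cohort layout of the motivating study design.
* **Missingness** is completely at random (`frac_missing`, default 2%).
  Real detection-p failures cluster by sample and probe; that mechanism is
  not modeled, so the tests say nothing about structured missingness.
* **Manifest.** A single toy chromosome with islands of width 1 kb on a
  10 kb lattice and one TSS per lattice period placed just inside the
  island, so the promoter-island rule has a computable positive set, and
  probe offsets (step 97, coprime with the lattice) sample every residue
  of the island period evenly — compartment fractions then have closed
  forms that the tests check exactly. Probes are planted uniformly over
  this layout, so the generator does **not** emulate the island-targeting
  of real tumor hypermethylation: compartment enrichment on simulated data
  is null by construction, and the Fisher machinery is instead verified by
  enumeration oracles and constructed profiles.
* **Expression.** A chosen fraction of planted genes receives a
  sign-opposite logFC (|logFC| ≥ 1.2, q < 0.05) in one randomly assigned
  table; everything else is null (|logFC| < 1, q ≥ 0.05). Effect-size
  distributions of real expression data are not modeled — the integration
  stage only consumes calls.
* **Survival.** Exponential event times (baseline median 40 months) with
  the hazard multiplied by `hazard_ratio` (default 3) for marker-high
  samples, and independent uniform censoring whose upper bound is solved
  by root finding so the expected censored fraction equals `censor_frac`
  (default 0.3). This is the simplest model under which Cox and log-rank
  recovery are well-defined; real survival data violate proportional
  hazards in ways the tests do not probe.

Identical seed and configuration reproduce every generator output
bit-for-bit; all randomness flows through the configuration seed.

What passing tests therefore show: the pipeline recovers planted effects
of the stated size under Beta noise at the stated sample sizes, its
statistics agree with independent brute-force oracles, and its null
calibration is nominal. What they do not show: robustness to batch
effects, tumor-purity mixtures, structured missingness, probe
cross-reactivity, or real compartment biology — none of which the
generator emulates.

# Test and verification sizes

The suite sizes its simulations to what the statistics need rather than to
array scale: oracle comparisons run on exhaustive small spaces (all
Mann–Whitney splits with combined n ≤ 10; all 2×2 tables with total ≤ 40;
a 10-sample Cox fixture against brute-force likelihood maximization),
recovery runs use 2000–5000 probes at 15 samples per group (effect 0.4,
5% planted) and 20 samples per survival arm (shift 0.3), and calibration
uses 10^4 Mann–Whitney and 10^3 log-rank null replicates. The acceptance
script (`scripts/acceptance.R`) re-runs the same computations from scratch
at a user-supplied seed.

# Known limitations

* Gene-symbol matching is exact (case-folded); no alias tables.
* The ANOVA screen's "two groups" reading and the exact-vs-asymptotic
  Mann–Whitney question are configuration choices, not settled facts.
* Probe counts from any given input are not comparable to published
  counts obtained on other cohorts with era-specific probe blacklists;
  the pipeline reports counts for the input it is given.
* No competing-risks modeling; censoring is assumed non-informative.
* The marker-dependent Breslow/ulceration covariates in the survival
  generator are a convenience for multivariate tests, not a calibrated
  clinical joint distribution.
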