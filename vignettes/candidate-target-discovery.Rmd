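---
title: "Methods: candidate-target discovery in glioblastoma stem cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: candidate-target discovery in glioblastoma stem cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsctargets)
```

# The screening problem

Glioblastoma stem cells (GSCs) are the case population; adult human
neural stem cells (NSCs, sometimes complemented by a fetal line) are the
control population — the closest non-malignant cell type, matched for
differentiation state and growth rate. A therapeutically attractive gene
is one that is *expressed in every tumor culture and not expressed in any
control culture*: such all-or-nothing behaviour is what a targeting agent
can exploit. On log2-scale microarray data, "not expressed" corresponds
to a log2 expression value below zero, which is why the screen is a sign
condition rather than a differential-expression statistic.

This package implements that screen and the verification stages around
it: co-expression structure, qPCR and western-blot confirmation, growth
assays, survival stratification and interaction-network queries, all
exercised end-to-end on seeded synthetic data with planted truths.

# The consistency filter

`consistency_filter(expr, threshold = 0)` selects gene $g$ iff

$$\max_{s \in \text{controls}} x_{gs} < t
\quad\text{and}\quad
\min_{s \in \text{cases}} x_{gs} > t .$$

Numerical conventions:

* **Strict inequalities.** A value exactly at the threshold excludes the
  gene; an all-zero matrix selects nothing. This makes the boundary
  behaviour testable and keeps the rule symmetric.
* **No missing values.** The filter's universal quantifier over samples
  is undefined under missingness, so the expression reader rejects NA
  tokens outright rather than guessing.
* **Threshold as a free parameter.** The default $t = 0$ is the natural
  cut on log2 data where 1 (linear) means "at the detection floor".
  Raising $t$ is *not* monotone in the selected set — it relaxes the
  control condition while tightening the case condition — so the
  threshold should be chosen on scale grounds, not tuned for set size.
* **Fold change** is reported as $2^{\bar{x}_{\text{case}} -
  \bar{x}_{\text{control}}}$, the antilog of the group-mean difference on
  the log2 scale. No formula is universal here; this is the standard
  quantity consistent with log2 input, and at zero simulation noise it
  returns the planted value exactly (planted means +2/−2 give FC 16).
* **Probe collapse** (`collapse_probes`): when rows are array probes,
  the maximum-mean probe per gene is kept before filtering, with ties
  broken by probe id. Max-mean is deterministic and favours the
  best-detected probe; filtering at probe level is also supported by
  simply not collapsing.

# Co-expression structure

All clustering uses the Pearson distance $d = 1 - r$ (range $[0, 2]$:
0 duplicates, 1 uncorrelated, 2 anti-correlated), with squared Euclidean
distance available as an alternative. Agglomeration is **average linkage
(UPGMA)**. The upstream tool this emulates names only the distance, so
the linkage had to be fixed by choice; average linkage is that tool's
common default and is kept constant for determinism. Items are sorted
lexicographically by id before merging, so the tree — and every cut of
it — is invariant to input order; equal-height merge ties are thereby
resolved identically regardless of presentation order.

`cut_modules(tree, k)` labels modules with roman numerals in order of
decreasing size (ties by smallest member id). `pca_overview` is a
gene-centered SVD of samples; components come out in non-increasing
variance order, and duplicated samples land on identical coordinates.

Zero-variance vectors make Pearson correlation undefined; the package
treats them as errors naming the offending items, never as silent NAs,
because a propagated NA would poison downstream summaries.

# Efficiency-corrected qPCR and the randomization test

With per-gene amplification efficiency $E \in (1, 2]$ (2 = perfect
doubling per cycle) and $\Delta C_q = \overline{C_q}(\text{control}) -
\overline{C_q}(\text{case})$, the relative expression of a target gene
normalized to a set $R$ of reference (housekeeping) genes is

$$\text{ratio} \;=\; \frac{E_{\text{target}}^{\Delta C_q(\text{target})}}
{\big(\prod_{r \in R} E_r^{\Delta C_q(r)}\big)^{1/|R|}} ,$$

which reduces to the classical $2^{-\Delta\Delta C_t}$ when all $E = 2$.
Conventions:

* **Replicates are averaged** to one $C_q$ per (gene, sample) before any
  group mean; the randomization test then reallocates *samples*, never
  replicates, avoiding pseudo-replication.
* **Reference aggregation** over multiple housekeeping genes uses the
  geometric mean, the standard behaviour when normalizing "to at least
  two" references.
* **All control cultures are pooled** into one reference group.
* **Default efficiency** is 2 when a table supplies none; per-gene
  overrides are honoured end to end.
* When all efficiencies are equal, a constant added to every $C_q$ of a
  sample (loading/input differences) cancels exactly through the
  references; with heterogeneous efficiencies the cancellation is only
  approximate, which is inherent to the correction, not an
  implementation artifact.

`reallocation_test` permutes the case/control labels over samples with
group sizes fixed and compares $|\log \text{ratio}|$ of each allocation
against the observed one (two-sided). When the number of distinct
allocations is at most `iterations` (default 2000) they are enumerated
exhaustively and the observed allocation is one of them; otherwise
`iterations` random allocations are drawn and the observed one is added
to numerator and denominator. Both branches make $p = 0$ impossible, and
the exhaustive branch makes the test exactly valid: under the null,
$P(p \le \alpha) \le \alpha$ by construction, which is why the measured
type-I error in the test suite sits below the nominal level.

Regulation calls are `UP` (ratio > 1, p < α), `DR` (ratio < 1, p < α),
else `NS`, with α = 0.05 by default.

# Western-blot quantification

$$\text{RPE} = \frac{\text{band} - \text{band background}}
{\text{loading-control} - \text{loading-control background}}$$

per protein and lane, with β-actin as the loading control. A band below
its own local background (an absent protein, as happens for genuinely
down-regulated targets) clamps to RPE 0 and is recorded in a QC
attribute rather than erroring; a non-positive loading-control net
intensity *is* an error naming the sample, since nothing can be
normalized against it. The loading control measured against itself is
identically 1.

**Correlation summaries** (`summarize_correlations`) aggregate per-gene
RNA–protein Pearson coefficients as mean ± SD with the **population SD
(divisor n)** convention — the convention under which the packaged
20-gene table reproduces its printed full-set aggregate (0.55 ± 0.41)
and its nine-gene module aggregate (0.75 ± 0.12). One caveat is recorded
here for transparency: for the three negative-correlation genes
(RAPGEF4, RHBDD1, MCC) the companion SD printed alongside the published
table (0.27) is not recoverable from the table's two-decimal
coefficients under either divisor convention (population gives 0.2254,
sample 0.2761); it was presumably computed on unrounded per-sample data.
The package reports what the printed coefficients yield.

The published table prints coefficient magnitudes; the accompanying
analysis states that RAPGEF4, RHBDD1 and MCC correlate *negatively*.
The fixture therefore stores magnitude and sign separately, and
`signed = TRUE` restores the sign before aggregating.

# Growth assays

$\text{PDT} = t \log 2 / (\log N_t - \log N_0)$ (days); the log base
cancels, counts may be rescaled freely, $N_t = N_0$ is undefined and a
shrinking culture yields a negative PDT with a warning flag. Multi-
passage records are summarized per culture as mean ± SD, matching how
growth panels are usually reported. Sphere assays summarize per-well
counts and per-sphere diameters (µm) as means with population SDs, and
`assay_correlation` relates assays across cultures (callers apply
transforms such as 1/PDT so that "faster growth" is a larger number).

# Survival stratification and comparison

`stratify` z-scores each module gene across patients, then either

* **cluster mode** (default): hierarchically clusters patients on their
  z-vectors — squared-Euclidean distance, average linkage — cuts at
  $k$ (default 3) and ranks clusters by mean module z-score
  (low / intermediate / high); or
* **tertile mode**: ranks patients by mean z-score and cuts into $k$
  equal-frequency groups.

The distance choice is deliberate and worth a note: a co-expressed
module moves a patient's whole z-vector up or down by a near-constant
amount, and *correlation* distance is blind to such shifts (it would
compare noise shapes, not expression levels). Euclidean distance on
z-scores is the level-sensitive metric, and with it well-separated
planted levels are recovered exactly. Both stratification readings are
defensible on real cohorts; they can disagree, which is why both modes
are exposed.

`km` is the product-limit estimator (computed via the survival package
and verified in the tests against a hand computation); the median is the
smallest event time with $S(t) \le 0.5$, undefined (NA) when the curve
never reaches 0.5. At tied times deaths are processed before
censorings, the standard convention.

`gbw_test` is the Gehan–Breslow–Wilcoxon weighted log-rank test: at each
distinct death time $t_j$ with $n_j$ at risk, $d_j$ deaths,

$$U = \sum_j n_j \Big(d_{1j} - d_j \tfrac{n_{1j}}{n_j}\Big), \qquad
V = \sum_j n_j^2\, \tfrac{n_{1j}}{n_j}\big(1 - \tfrac{n_{1j}}{n_j}\big)
d_j \tfrac{n_j - d_j}{n_j - 1},$$

with $U^2/V \sim \chi^2_1$ two-sided. The at-risk weight $w_j = n_j$
emphasizes early deaths, appropriate in a disease whose median survival
is around a year. The chi-square reference is an approximation; on tiny
samples the tests compare it against the exact reallocation distribution
and agreement is bounded by that distribution's discreteness.

`logistic_screen` fits one maximum-likelihood logistic regression per
probe (IRLS via `glm`) and reports Wald p-values — the usual choice for
univariate screening — adjusted by Benjamini–Hochberg step-up
(`bh_adjust`, default q = 0.10). Complete separation is flagged and the
p-value withheld; because `glm` can terminate "converged" on separated
data with an absurd slope and an enormous Wald standard error, slopes
with $|\beta| > 15$ (odds ratios beyond $10^6$) or SE > 100 are also
treated as separation. A constant probe reports slope 0, p = 1 by
convention.

# Interaction graphs

Edge lists (typed: protein–protein, protein–DNA, protein–RNA, genetic)
build an undirected graph; self-loops are dropped and duplicates
collapse to one edge per unordered pair and type, so all queries are
invariant to row order and duplication. Edge types are carried but mixed
by default — the curated source mixes them — with an optional type
filter. `common_interactants(g, a, b)` is the neighbor-set intersection
minus the endpoints, symmetric in (a, b). `hubs` uses an explicit
convention, since the source names hubs without a rule: by default a hub
strictly exceeds mean degree + 1 population SD (so a regular graph has
no hubs, and the centre of a star is one); an explicit `min_degree` is
an inclusive override.

The packaged highlighted-interaction table expands as: a direct pair
contributes the edge (a, b); each intermediary $x$ of a pair contributes
(a, x) and (x, b); records that are both direct and mediated contribute
all three. One consequence is documented rather than hidden: the table
lists 13 intermediaries between STAT3 and EZH2, but it *also* records
ubiquitin C binding both proteins directly, so the neighbor-set
intersection on the full graph has 14 members. The EGFR–PBK pair is
unaffected (11 either way). The package reports what the graph contains.

# The synthetic-data generators

`sim_config()` defaults encode the study conditions this package
emulates:

| Parameter | Default | Meaning |
|---|---|---|
| `n_case` / `n_control` | 9 / 5 | GSC vs NSC culture counts of the discovery design |
| `planted_genes` | 20 ids | consistent genes planted at log2 means +2 (case) / −2 (control) |
| `noise_sd` | 0.5 | log2 within-group SD; clear on/off separation with realistic array noise |
| qPCR `fold_changes` | published qPCR fold changes of the 20-gene set | planted Pfaffl ratios |
| qPCR `efficiency` | 2 | perfect doubling; per-gene override |
| western `rpe_case` | published western fold changes | planted RPE, control RPE 1 |
| survival `n_patients` | 200 | cohort scale of the expression/survival analysis |
| survival `baseline_median_days` | 383 | low-group median of the emulated cohort |
| survival `hazard_multiplier` | 2 | high vs low group hazard ratio |
| survival `censoring_rate` | 0.2 | expected censored fraction |

Generator mechanics are chosen so that every estimator *inverts* its
generator at zero noise: case-group $C_q$ is lowered by $\log(\text{FC})
/ \log(E)$ cycles so the Pfaffl ratio returns FC exactly; bands are
true RPE × loading-control × lognormal noise + background so `rpe`
returns the plant; survival times are exponential with group-specific
hazards so medians scale as $1/\text{hazard}$. Module members share a
per-sample latent factor, $x = \mu + \sigma(\sqrt{\rho} f_s +
\sqrt{1-\rho}\, \epsilon)$, giving pairwise correlation $\rho$ and
marginal SD $\sigma$. Per-sample $C_q$ offsets emulate RNA-input
differences and cancel through the references. Randomness is threaded
through one master seed with fixed per-stage offsets, so identical
configs give identical outputs and stages are independently
reproducible; the generator's RNG state never leaks into the caller's
session.

What the generators do **not** emulate: probe-level microarray
structure, batch effects, heteroscedastic array noise, non-exponential
hazards, informative censoring, or correlated technical replicates.
Passing tests therefore demonstrate correctness of the computations and
recoverability of planted structure under idealized noise — not
robustness to every artefact of real cohorts.

# Problem sizes used by the test suite

The suite runs at sizes chosen to make sampling error negligible
relative to the asserted tolerances while staying desk-scale: oracle
equivalence of the filter up to 10^4 genes; module-correlation recovery
at 50 samples; null-hazard medians at 2000 patients per arm; the
survival end-to-end check at 200 patients per arm over 200 replicates
(asserting the planted high-hazard group shows the shorter median in at
least 95% of replicates and a significant weighted log-rank p in at
least 80%); and randomization-test calibration over 2000 null genes with
exhaustive 5-vs-5 enumeration.

# Known limitations

* The stratification contract (clustering versus tertiles) is a genuine
  analytical choice; published cohort medians depend on the grouping
  rule used upstream and are not reproduced from packaged data.
* The hub rule and the probe-collapse rule are documented conventions,
  not inferences from data.
* The reallocation test is exact only in its exhaustive branch; the
  Monte-Carlo branch inherits simulation error of order
  $1/\sqrt{\text{iterations}}$.
* Cox proportional-hazards modelling, array preprocessing (RMA),
  image-based quantification and live database retrieval are out of
  scope; files and fixtures stand in for the latter.
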