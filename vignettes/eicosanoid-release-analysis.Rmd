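---
title: "Permutation analysis of stimulated whole-blood eicosanoid release"
author: "eicoperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation analysis of stimulated whole-blood eicosanoid release}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eicoperm)
```

## The assay and the statistical problem

Targeted LC-MS/MS lipidomics panels quantify a few dozen eicosanoids —
prostaglandins, thromboxanes, leukotrienes, HETEs, epoxy- and dihydroxy
fatty acids — in ng/ml. In a whole-blood stimulation design, each subject
contributes two measurements per metabolite: a *baseline* concentration in
unstimulated EDTA plasma, and a *stimulated* concentration in the
supernatant of heparinized blood incubated with zymosan, which activates
leukocytes through TLR2 and mobilizes arachidonic acid. The scientific
quantity of interest is the *net release capacity* of the subject's
leukocytes, compared across clinical groups (healthy controls,
mild-to-moderate asthma, severe asthma, and the severe group stratified by
permanent oral corticosteroid use).

Three features of such data drive every choice in this package:

1. **Left-censoring.** Many analytes sit near the limit of detection
   (LOD); cells below it are reported only as "below LOD".
2. **Nuisance variation.** Stimulated release scales with the number of
   responding cells, and leukocyte counts differ systematically between
   asthmatics and controls; basal circulating levels differ between
   subjects.
3. **Small, skewed, tied samples.** Concentrations are positive and
   right-skewed, and substitution of censored values creates ties, so
   normal-theory tests are off the table.

## The preprocessing model

For subject $i$ and metabolite $j$, with stimulated concentration
$s_{ij}$, baseline concentration $b_{ij}$ and white-blood-cell count
$w_i$ (in $10^6$/ml), the tested quantity is the net release

$$ y_{ij} \;=\; \frac{s^*_{ij} - b^*_{ij}}{w_i} \quad
   \text{[ng per } 10^6 \text{ leukocytes]}, $$

where $^*$ denotes censored-value substitution. Negative values are
retained: clipping at zero would create artificial ties and distort
ranks. Substitution happens *before* subtraction and uniformly in both
matrices.

**Detection filter.** Within each two-group contrast, a metabolite is
excluded when at least 80% of samples are below the LOD in *both*
groups (the boundary excludes). The filter is evaluated per contrast on
the matrix being analyzed (the stimulated matrix for the release
analysis), because a metabolite well measured in either compared group
still carries rank information.

**Substitution schemes.** Three are provided, selected by
`scheme`/`--censor`:

* `zero` (default): censored cells become 0.
* `half_lod`: censored cells become LOD/2.
* `km`: censored cells become the metabolite's conditional mean below
  the LOD under the reversed Kaplan–Meier distribution.

For the `km` scheme the left-censored sample is flipped
($y = -x$, censored cells right-censored at $-\mathrm{LOD}$), the
product-limit estimator is applied (via `survival::survfit`), and the
result is flipped back. With a single LOD per metabolite the
product-limit cannot resolve the shape of the sub-LOD tail; the package
adopts the convention that the unresolved mass sits at the midpoint
LOD/2 of the censoring interval $[0, \mathrm{LOD})$ — concentrations are
bounded below by zero and the data say nothing more. A consequence worth
stating plainly: when no detected value falls below the LOD, `km`
imputation coincides with `half_lod` imputation cell by cell. That is
not an accident — it is the same mechanism that makes the substitution
choice immaterial for the downstream rank tests (see *Invariances*
below), and the reason sensitivity analyses across these schemes agree.
The estimator is still fully general: when a detected value lies below
the nominal LOD (as happens with instrument-flagged real data), the
product-limit redistributes mass non-trivially, and the package computes
it correctly.

**Invariances.** Because inference is rank-based, replacing all censored
cells of a metabolite by *any* common constant below every detected
value leaves every Wilcoxon statistic and permutation p-value identical.
The test suite asserts this both as a property (zero vs LOD/2 vs other
constants) and end-to-end on generated cohorts. Similarly, a common
positive rescaling (e.g. equal WBC counts) leaves all results unchanged.

## Metabolite-level inference

For a contrast with groups $A$ and $B$ ($n_A + n_B = n$), the statistic
is the Wilcoxon rank sum $W$ of group $A$ with midranks for ties, and
two-sided evidence is $|W - n_A(n+1)/2|$, its absolute deviation from
the null expectation — symmetric, tie-safe, and exchangeable under
permutation.

The null distribution is obtained by permuting group labels. One *joint
ensemble* of label assignments — identity first, then $B$ (default
10,000) uniformly random re-assignments preserving group sizes — is
shared by all metabolites of a contrast, which preserves their
correlation and is what makes resampling-based multiplicity adjustment
valid. P-values follow the $(1 + b)/(B + 1)$ convention, counting ties
as at-least-as-extreme; the test is exactly valid and $p \ge 1/(B+1)$.
Random assignments are sampled independently (repeats possible) rather
than without replacement over the assignment space: with $B = 10^4$ and
realistic $n$, collisions are negligible and sampling stays $O(B)$.

When the total sample size is at most `exhaustive_max_n` (default 12),
the implementation enumerates all $\binom{n}{n_A}$ assignments instead;
p-values are then exact enumeration p-values and, for tie-free data,
equal the classical exact Wilcoxon test (asserted against both a
brute-force enumerator and `wilcox.test(exact = TRUE)`).

Subjects missing a metabolite's value (not measured — distinct from
censored) are dropped pairwise for that metabolite; the ensemble's label
rows are restricted to the observed subjects, and the per-row label
count enters the centering term, so the permutation test stays valid on
the reduced sample. Selected subjects are ordered by id before the
ensemble is built, making results invariant to input row order.

### Step-down multiplicity adjustment

The default adjustment is resampling-based **step-down minP**
(Westfall–Young type), the natural companion of a joint permutation
ensemble. Every statistic is double-ranked within its own ensemble row
to give per-permutation p-values
$p_{jb} = \#\{b' : S_{jb'} \ge S_{jb}\}/(B+1)$ (so the identity column
is exactly the raw p-value); hypotheses are ordered by raw p; for each
permutation the successive minima over the remaining hypotheses are
formed; the adjusted p-value is the fraction of permutations whose
min-p undercuts the observed raw p; monotonicity is enforced along the
ordering. Two properties follow by construction and are tested:
adjusted p-values never fall below raw ones, and for perfectly
correlated (duplicated) metabolites the adjustment vanishes — the
correlation-adaptivity that rank-count procedures like
Benjamini–Hochberg lack. BH step-up (`method = "bh"`, via
`stats::p.adjust`) is provided as a standard cross-check; on simulated
cohorts with planted effects both procedures keep the false-discovery
proportion at or below the nominal level. The adjustment family is one
contrast (recorded in the run manifest); adjusting across contrasts
jointly would mix exchangeable and non-exchangeable label sets.

Note minP controls the family-wise error rate, which implies FDR
control; it is the strictly more conservative of the two options.

## Pathway-level inference

Functional class scoring aggregates metabolite-level evidence within
each biosynthesis pathway (COX, 5-LOX, 12-LOX, 15-LOX, CYP).
Auto-oxidation products (AUTOX) are carried in the panel as a real
pathway label but never scored: they are exposure/handling markers, not
enzymatic signal. Dual-annotated metabolites (e.g. 5-LOX/15-LOX) count
in every pathway they carry by default (`dual = "all"`); since published
membership counts cannot always be reconstructed unambiguously,
membership is data, not code, and a `dual = "drop"` variant exists.

The combining function is **Tippett's minimum p**: the pathway statistic
is the smallest member p-value. Its null calibration does *not* use the
independence form $1-(1-t)^k$ (which the test suite verifies only as the
closed form for independent uniforms); instead the pathway p-value is
computed on the same joint ensemble: for each permutation $b$ the member
per-permutation p-values are combined, and

$$ p_{\text{pathway}} = \frac{1 + \#\{b \ge 1 : \min_b \le
   \min_{\text{obs}}\}}{B + 1}. $$

Because the labels are permuted jointly, this is a *self-contained*
test (null: no member is associated with the grouping) that inherits
the inter-metabolite correlation. Two exact reductions are asserted:
a singleton pathway reproduces its member's raw p-value, and duplicated
members change nothing. Pathway p-values across the 4–5 pathways are
then adjusted with the same step-down machinery.

## The synthetic cohort generator

No participant-level data are published for this kind of assay, so the
generator is a first-class module: it encodes the statistical structure
the analysis assumes and makes every downstream stage testable.

For metabolite $j$: baseline $b_{ij} \sim \mathrm{LogNormal}$ with
median $m_j$ and log-sd $\sigma_j$; per-cell release $r_{ij} \sim
\mathrm{LogNormal}$ (ng per $10^6$ cells), multiplied by any subgroup
fold-changes; stimulated value $s_{ij} = b_{ij} + w_i\, r_{ij}$; WBC
$w_i$ normal truncated at $0.5 \times 10^6$/ml (counts are reported as
mean ± SD, and truncation respects positivity without re-skewing).
Cells below the metabolite's LOD are flagged censored and stored as 0.
Everything is reproducible bit-for-bit from the config seed.

The choices are deliberate:

* **Log-normal concentrations** — positive, right-skewed (reported SDs
  often exceed means, i.e. CV > 1); downstream inference is rank-based,
  so the tail shape is low-risk.
* **Additive stimulated = baseline + release** — the pipeline's baseline
  subtraction is then *exactly* the right deconfounder at fold-change 1.
* **Release proportional to WBC** — the pipeline's WBC normalization is
  then exactly the right correction; this is the implicit assumption of
  normalizing release to the leukocyte count.
* **Effects as multiplicative fold-changes on the release median of a
  target subgroup** (moderate, severe, severe_ocs, severe_no_ocs,
  control) rather than on a contrast pair: a generative model needs
  group-level parameters, and every reported direction maps 1:1 onto a
  subgroup.

`reference_config()` packages the study design: 63 controls, 108
mild-to-moderate, 90 severe (44 of them on OCS); WBC 6.02 ± 1.46
(controls) and 7.87 ± 2.61 (asthma) ×10^6/ml; the 67-analyte panel with
baseline medians anchored to published control plasma means; and planted
effects reproducing the reported directions (LTE4 release up ×3 in
OCS-naive asthmatics, 15-HETE up ×2 in mild-to-moderate and down ×0.7 in
severe disease, all COX-pathway release down ×0.4 under OCS, 11-HETE and
12-HHT down ×0.6 in OCS-naive severe disease, PGE2/TXB2 mildly down
×0.8 there — directions significant in the source figures get strong
folds, reported-but-not-significant trends get mild ones). LODs are
synthetic (true assay LODs are unpublished): one fifth of the control
mean for plasma-detectable analytes, 0.005 ng/ml otherwise. Ten
plasma-undetectable analytes (leukotriene intermediates and minor
prostanoids) are given release scales above their LOD, and the
remaining 16 stay silent, so that 51 of 67 analytes are detectable
after stimulation — mirroring the assay's observed detection pattern.

What the generator does *not* emulate: batch and chromatographic drift,
within-subject correlation beyond the shared baseline term,
heavy-tailed contamination, and correlated metabolites within a pathway
(members are independent under the null). Passing tests therefore
validate the *statistical machinery* under the stated model, not the
assay chemistry; with correlated members the minP and Tippett machinery
is exactly the part designed to adapt, and the duplicated-column tests
cover the extreme of that regime.

One emergent and realistic artifact is worth knowing about: for
analytes hovering near the LOD, a group with higher WBC gets censored
less often in the stimulated matrix, so zero-substitution can induce
genuine distributional group differences even at fold-change 1. This is
a property of censoring near the detection limit, not of the test; it
is one reason pathway-level signals should be read alongside the
per-metabolite directions.

## Numerical and interface choices

* P-value floors: raw p ≥ 1/(B+1); all reported p-values are exactly
  reproducible from the seed recorded in the run manifest.
* Ties: midranks in the statistic; ≥ comparisons when counting extreme
  permutations (conservative); stable ordering in the step-down pass.
* Degenerate inputs: constant data give p = 1; all-censored metabolites
  under `km` fall back to zero substitution with a warning; empty
  pathways are dropped with a message; an empty group after
  missing-value removal is an error, not a silent skip.
* The detection filter's boundary is exclusive-by-inclusion: censored
  fraction exactly 0.8 in both groups excludes ("at least 80%").
* Output determinism: identical run configurations (including seed)
  produce byte-identical result trees; the manifest records seed, B,
  scheme, threshold, adjustment and contrast set.

## Problem sizes used in the packaged studies

The test suite and `scripts/acceptance.R` run Monte-Carlo studies sized
for tight-but-affordable checks, chosen once: calibration on 1,000 null
cohorts (10 metabolites, 20/group, B = 2,000) against the 99% binomial
envelope [0.032, 0.068]; FDR control on 200 replicates of a 20-metabolite
design (15 null, 5 at fold 3, 30/group, B = 1,000); pathway selectivity
on 100 replicates of a four-pathway design with one fold-4 pathway;
Tippett's closed form at 10,000 draws against the 99% DKW band. The
calibration study uses a config with negligible censoring by design: it
is an oracle for the permutation machinery itself, whereas heavy
censoring would fold tie-induced conservatism into the measurement.

## Known limitations

* The self-contained pathway null means a pathway can score well because
  of a single strong member; the Tippett statistic is by construction a
  best-member detector. Fisher/Stouffer-type combiners would weight
  breadth differently and are not implemented.
* `km` substitution imputes a single conditional mean per metabolite;
  multiple imputation and censored-likelihood (Tobit-type) models are
  out of scope.
* Permutation is marginal per contrast; paired, stratified, or
  covariate-adjusted permutation schemes are not provided.
* With B = 10,000 the smallest attainable raw p is ~1e-4; adjusted
  pathway p-values are floored accordingly.
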