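---
title: "Methods: cumulative methylation index panels, locked-threshold evaluation, and the synthetic cohort model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CMI panels and locked-threshold evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmipanel)
```

## The measurement model

Quantitative multiplex methylation-specific PCR (QM-MSP) reports, for each
gene in each sample, the number of methylated and unmethylated template
copies. The per-gene quantity analysed throughout is percent methylation,

$$\%M \;=\; 100 \cdot \frac{\#\,\text{methylated copies}}
{\#\,\text{methylated} + \#\,\text{unmethylated copies}},$$

a value in $[0, 100]$. A total of zero copies is an *undefined measurement*
(assay dropout), and `percent_methylation()` raises an error rather than
reporting 0 %M: zero methylation and a failed assay are different facts, and
conflating them would bias every downstream summary toward the negative
class. For the same reason missing cells in a `methylation_matrix` are never
imputed; any operation that needs them fails loudly and the caller decides
whether to drop the sample (the convention used for the one
insufficient-DNA sample excluded from the reference cohort this package's
summaries describe).

The classification score for a panel $P$ of genes is the **cumulative
methylation index**,

$$\mathrm{CMI}_P(s) \;=\; \sum_{g \in P} \%M_{s,g} \in [0,\; 100\,|P|],$$

a plain sum with no weights. Summation makes the score additive over
disjoint panels and monotone in every marker, which is what lets a panel
tolerate individual marker dropouts in carcinomas (any one high marker can
carry the sum past the threshold) while background in normals accumulates —
the reason the selection procedure polices normal-tissue background so
strictly.

## Three-stage marker selection

`select_panel()` reduces a candidate marker set to a minimal panel in a
fixed order, mirroring how such panels are curated in practice:

1. **Significance** (`filter_significant`): a marker must show
   significantly *higher* %M in carcinoma than in normal tissue by a
   two-tailed Mann-Whitney test at $\alpha = 0.05$. The direction condition
   (carcinoma median $\ge$ normal median) is explicit: a marker that is
   significantly methylated the wrong way should not survive on its
   p-value alone.
2. **Background** (`filter_background`): the normal-class 75th percentile
   of %M quantifies background; a marker at or above 10 %M is eliminated.
   The boundary is *inclusive* — a marker whose normal q75 is exactly
   10 %M is removed. With the packaged reference summaries this inclusive
   rule is what eliminates COL6A2 (normal q75 exactly 10) together with
   TM6SF1 (15) and ZNF671 (16).
3. **Ranking** (`rank_and_select`): survivors are ordered by descending
   carcinoma 75th-percentile %M and the top $k$ (default 6) become the
   panel. The 75th percentile, not the median, is the ranking statistic:
   for markers that are strongly methylated in a *subset* of tumours the
   upper quartile captures detection-relevant signal that the median
   misses (compare ARHGEF7: carcinoma median 8, q75 33).

Ties in the ranking statistic are broken by descending carcinoma median,
then lexical gene id, and every tie event is recorded in the result — the
procedure is deterministic by construction, including output order.

The filters accept either raw data (via `summarize_markers()`) or an
injected table of per-gene summaries and p-values. The packaged
`reference_marker_summaries()` table makes the published worked example a
first-class fixture: running the three stages on it discards APC and
HIST1H3C (p-values 0.2662 and 0.3959), removes the three high-background
markers, and ranks the surviving eight
TMEFF2 > GPX7 > MAL > ARHGEF7 > TWIST1 > AKR1B1 > HIN1 > GAS7, of which the
top six form the tissue panel.

```{r selection}
sel <- select_panel_from_summaries(reference_marker_summaries())
sel
```

## Percentile convention

Quartiles follow the rank $k = p\,(n+1)$ rule with linear interpolation
(`stats::quantile` type 6), the convention of the commercial statistics
software prevalent in clinical-biomarker work, so summaries computed from
raw data are comparable with published tables produced by such software.
The convention is a knob (`percentile_method`) because the difference
between type-6 and type-7 quartiles is material at the cohort sizes
involved (tens of samples per class).

## Rank test

`mann_whitney()` computes $U$ as pairwise wins plus half-ties. Exact mode
enumerates all $\binom{n_1+n_2}{n_1}$ assignments of the observed pooled
multiset — so ties need no special theory — and doubles the smaller tail,
capping at 1; enumeration is vectorised and permitted up to a pooled
$n = 20$. The default switches to the tie-corrected normal approximation
with continuity correction above pooled $n = 12$. A pooled sample that is
entirely constant carries no rank information: $p = 1$ by convention, and
the result is flagged degenerate rather than silently returned. The
identity $\mathrm{AUC} = U/(n_1 n_2)$ ties the rank test to the ROC module
and is verified on random instances in the test suite.

## ROC analysis with a locked threshold

The decision rule is `score >= threshold` ⇒ carcinoma. Candidate
thresholds are midpoints between consecutive distinct pooled scores plus
$\pm\infty$ sentinels. Midpoints make the ≥-vs-> distinction vacuous on
observed data and are the convention that produces half-integer thresholds
from integer-valued CMI data (the published panel thresholds 88.5, 26.0,
8.5 and 3.5 are all midpoints of this kind).

`lock_threshold()` maximises training sensitivity subject to a specificity
floor (default 90%); among equally sensitive candidates it takes the
*largest* threshold, the conservative choice that keeps the most distance
from the normal scores. The $+\infty$ sentinel guarantees feasibility for
any floor. The returned object is the only input `evaluate_locked()`
accepts, so the train-lock-test discipline is enforced by artifact
structure — test scores cannot alter the threshold, and the command-line
`evaluate` subcommand refuses to run without a threshold file written by
`lock`.

Test-set reporting: confusion counts at the locked value; sensitivity and
specificity with Clopper–Pearson exact binomial 95% CIs; AUC with a DeLong
CI, falling back to a seeded stratified percentile bootstrap (2000
replicates) when the DeLong variance is zero (perfectly separated test
data, where AUC $= 1$ exactly); and prevalence-adjusted predictive values

$$\%PPV = 100\,\frac{se \cdot p}{se \cdot p + (1-sp)(1-p)}, \qquad
\%NPV = 100\,\frac{sp\,(1-p)}{(1-se)\,p + sp\,(1-p)},$$

with accuracy $100\,(se \cdot p + sp\,(1-p))$, at a default population
prevalence of 1% appropriate for a screening context. A predictive value
whose numerator and denominator both vanish (PPV of a never-positive test)
is reported as undefined, not as a number. CI methods for proportions vary
across software; the Clopper–Pearson choice here is exact and conservative,
and CI numerics are deliberately not part of the package's acceptance
surface.

## Clustering prescreen

The candidate-locus screen clusters probes and samples of a beta-value
matrix (array-scale methylation fractions in $[0,1]$ — a distinct type from
%M, to keep the two unit systems from mixing) by unweighted average linkage
(UPGMA) on Euclidean distances of unadjusted beta values. "Average
linkage" is ambiguous across software; the unweighted variant
$d(A \cup B, C) = (|A| d(A,C) + |B| d(B,C))/(|A|+|B|)$ is used here and is
validated in the tests against a brute-force oracle that recomputes every
inter-cluster mean from the raw distance table at every merge. Probes with
any missing value are dropped (with a logged count), not imputed.

Because the published cluster pick was visual, `candidate_cluster()`
operationalises it: cut the probe dendrogram (into $k$ clusters or at a
height), take the cluster with the highest mean differential score (mean
carcinoma beta minus mean normal beta), and filter members by a per-probe
score floor. Judgment calls outside the winning cluster are supported by an
explicit manual include-list rather than automated heuristics — the two
loci added by inspection in the reference study are exactly that kind of
call.

## MSI association

`msi_differential()` compares %M between microsatellite-unstable and
-stable carcinomas per gene, excluding unknown-status samples internally
and deterministically. Raw two-tailed p-values are the primary output,
matching standard practice for this kind of exploratory association; a
Bonferroni column is emitted alongside, clearly labelled as an extension,
so the multiplicity burden of testing a full panel is visible.
`msi_cmi_test()` applies the same comparison to panel-level CMI.

## The synthetic cohort model

Patient-level data behind the reference summaries are not distributed, so
the package ships a generator that reproduces their *marginal*
distributions. Each gene-class pair is modelled by the piecewise-linear
quantile function through $(0, \min), (0.25, q_{25}), (0.5, \mathrm{med}),
(0.75, q_{75}), (1, \max)$; `sample_gene()` draws by inverse transform.
This representation was chosen over parametric fits (beta, lognormal)
because it honours the five published numbers *exactly* by construction —
including point masses where adjacent summary values coincide (e.g. genes
with $q_{25} = 0$) — and because it bounds support: every draw lies in
$[\min, \max]$. Two structural consequences matter:

* **Forced separation.** MAL's carcinoma support $[9, 71]$ and normal
  support $[0, 7]$ are disjoint, so any simulated cohort is perfectly
  separable on MAL alone: single-marker AUC 1.000 and 100% sensitivity at
  any threshold locked under a 90% specificity floor. This is a property
  of the published summaries, not of a tuned simulation, and it is what
  the acceptance script recomputes.
* **Boundary fragility.** COL6A2's normal $q_{75}$ equals the background
  cutoff exactly, so in continuous simulated data its empirical background
  falls on either side of the inclusive cutoff with roughly equal
  probability at any cohort size; similarly AKR1B1 and HIN1 rank only
  3 %M apart at carcinoma $q_{75}$, within sampling noise at realistic
  $n$. End-to-end selection on simulated cohorts therefore reproduces the
  *interior* of the published decision (the five safely-separated panel
  genes, and both background eliminations that sit clear of the cutoff)
  but not the boundary calls; the deterministic worked example above is
  the faithful reproduction of those. The tests assert exactly this split.

Genes are sampled independently within class — only marginals are
published, independence is the minimal completion, and positive
correlation among hypermethylated genes would only widen panel-level CMI
separation, so the independence assumption is conservative for panel
claims. Simulated marginals also cannot encode within-cohort rank overlap:
a marker whose printed test was non-significant despite a heavy carcinoma
tail (HIST1H3C) *will* test significant in large simulated cohorts. The
generator is therefore a tool for exercising the pipeline under known
truth, not a re-creation of the patient cohort, and passing simulation
tests should be read accordingly.

Remaining generator defaults, stated once: cohort sizes 30 carcinoma / 23
normal (the reference training set); MSI fraction 1/3 of carcinomas
(20 MSI / 40 MSS in the reference tissue series); ages truncated-normal,
mean 69 (carcinoma) / 66 (normal) years, sd 8, range 40–95, loosely
matching the reference demographics; plasma cohorts 20/20 with normal
background 0 %M with probability 0.9 (else uniform on $[0,2]$) and
carcinoma signal zero-inflated gamma (shape 2, scale 8 %M, 20% zeros) —
the plasma numbers are invented operating conditions for exercising the
8- and 5-gene plasma workflow and are labelled as such, with no claim of
fidelity to cell-free-DNA assay chemistry.

`split_cohort()` reproduces the randomised age-balanced train/test design:
stratified by class and within-class age tertile, sizes within one sample
per stratum, and redrawn (bounded retries, best kept) until class-wise
mean ages differ by at most 3 years.

## Problem sizes and numerical tolerances in the shipped tests

The test suite runs the property checks at sizes chosen to make each check
statistically meaningful on one CPU in well under the package's test
budget: 200 random instances for the AUC/U identity (tolerance 1e-12,
machine-precision agreement of two exact formulas); exact-vs-approximate
rank-test agreement within 0.02 at $n_1 = n_2 = 8$; the UPGMA oracle on all
random instances up to $n = 8$; 500 random locked-threshold instances for
the specificity-floor guarantee; quantile recovery of every reference
summary cell within ±1 %M at $n = 10^5$ draws; and median recovery of the
full cohort generator within ±3 %M at $n = 2 \times 10^4$ per class — the
size at which the sampling error of the median is small against the
tolerance even for the steepest quantile functions in the table (APC's
rises ~230 %M per unit quantile just above its median knot, which makes
median recovery at small $n$ a property of the sampler's noise, not of its
correctness). MSI recovery of a planted +20 %M shift (20 MSI vs 40 MSS) is
asserted by majority vote across 20 seeded replicates — per-replicate
exact recovery is not a property this design can promise, since nine null
genes tested at $\alpha = 0.05$ produce a false flag in roughly a third of
replicates, and the widest-spread shifted gene (GPX7, carcinoma IQR
52 %M) detects in under 90% of replicates; the vote separates shifted from
null genes by a wide margin. Type-I error of the rank test is checked
against $\alpha$ over 1000 null replicates.

## Limitations

* Marginal simulation cannot validate claims that depend on joint
  structure (gene-gene correlation, within-sample rank overlap); see
  above.
* Published confidence intervals from other software are not reproduced
  bit-for-bit; the package states its CI methods explicitly instead.
* The clustering prescreen validates against constructed block designs;
  the original array screen's exact cluster boundary is a visual call that
  no algorithmic cut can be proven to match.
* Dataset-level locked thresholds (88.5 / 26.0 / 8.5 / 3.5 CMI) are
  properties of unavailable patient-level data and are treated as inputs
  (panel configuration), not as reproducible outputs.
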