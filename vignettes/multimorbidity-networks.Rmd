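---
title: "Methods: sex-stratified multimorbidity networks in matched diabetes cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified multimorbidity networks in matched diabetes cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnet)
```

`mmnet` implements a comparative network analysis of multimorbidity in a
type 1 diabetes (T1DM) cohort against a 1:1 matched type 2 diabetes (T2DM)
cohort, stratified by sex. This vignette is the package's account of the
method: the model and its assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, the numerical
conventions, and the design decisions taken where the procedure leaves room.

## Study design stage

**Index date.** A patient's index date is the *earliest* diagnosis date
carrying any index-disease code (`assign_index_date()`). Patients with no
qualifying record are excluded with a logged reason, not an error.
Comorbidity extraction keeps codes recorded **on or after** the index date:
first-visit coding routinely includes concurrent diagnoses, and a strict
"after" would discard the entire index encounter. This on-or-after reading
is an assumption, exposed here rather than buried in code.

**Matching.** `match_cohorts()` forms `min(n_cases, n_comparators)` pairs
within every exact (sex, index age in years) stratum. Selection within a
stratum is a seeded uniform draw without replacement over ids sorted
lexicographically first, which makes the pairing deterministic for a fixed
seed and invariant to input row order. A stratum with no comparators yields
unmatched cases with a reason, never an exception.

**Observed follow-up** is the calendar-day count from index date to last
recorded visit divided by 365.25, in years.

**Comorbidity scope.** Conditions are restricted to ICD-10 chapters I–XIV
(the chapters capturing well-defined diseases, excluding symptom/sign and
external-cause chapters), the index disease itself is excluded (its
specific complications, e.g. diabetic nephropathy, remain eligible — they
are legitimate network nodes), and a condition is retained only where its
prevalence is **≥ 1% (inclusive)** within a diabetes-type cohort. The filter
is applied per cohort *pooling sexes*, and the resulting code list is
shared by that cohort's male and female networks: this is the reading under
which a cohort's two sex-specific networks share one node set, which is
what published per-subgroup node counts reflect. Multimorbidity is flagged
as ≥ 2 retained conditions.

## Co-occurrence statistics and the SCI cut-off

Within one diabetes-type × sex subgroup of $N$ patients, for conditions
$i, j$ with marginal counts $c_i, c_j$ and joint count $c_{ij}$:

$$\mathrm{SCI}_{ij} = \frac{c_{ij}}{\sqrt{c_i c_j}}, \qquad
\Phi_{ij} = \frac{c_{ij} N - c_i c_j}{\sqrt{c_i c_j (N - c_i)(N - c_j)}},
\qquad
t_{ij} = \frac{\Phi_{ij}\sqrt{c_{ij} - 2}}{\sqrt{1 - \Phi_{ij}^2}}.$$

SCI is the cosine similarity of the two patient sets (range $[0,1]$,
independent of $N$); $\Phi$ is exactly the Pearson correlation of the two
binary indicator vectors (the test suite asserts this equivalence against
`cor()` on random fixtures); $t$ screens significance at $t > 1.96$
($p < 0.05$, two-sided).

**Degrees of freedom in $t$.** The formula uses $c_{ij} - 2$, the joint
count, rather than the conventional correlation-test $N - 2$. We implement
the $c_{ij}$-based form as the procedure's printed convention — it is far
more conservative (a pair needs a sizeable *joint* count, not merely a
large cohort, to reach significance) — and expose the conventional
alternative via `t_value(..., df_from = "N")` for sensitivity analyses.
Pairs with $c_{ij} < 3$ have an undefined $t$ and count as non-significant;
$|\Phi| = 1$ maps to an infinite $t$ (always significant).

**Cut-off derivation** (`derive_cutoff()`), per subgroup:

1. compute SCI and $\Phi$ for every unordered pair of retained codes;
2. $q$ = number of pairs with $c_{ij} > 0$;
3. $e$ = number of pairs with $t > 1.96$ **and** $c_{ij} > \sum c_{ij}/q$
   (the mean joint count over the $q$ positive pairs, strict inequality);
4. keep the **top-$e$ pairs ranked by SCI** among positive pairs; the SCI
   cut-off is the $e$-th ranked SCI ($+\infty$ when $e = 0$, an empty
   network rather than an error).

Step 4 is the unique reading under which the SCI network and the
$\Phi$-based screen contain the same number of positively associated
pairs, which is the principle the thresholding is built on. Two
consequences are worth stating plainly. First, because the mean rule is a
strict inequality, $e = q$ is impossible for any nonempty pair set (no set
lies entirely above its own mean; a lone positive pair can never pass), so
"keep everything" is not an attainable outcome. Second, the top-$e$ set is
ranked by SCI, *not* by $t$: a pair that passed the significance screen can
be displaced from the final edge set by a non-significant pair of higher
SCI (typically a high-prevalence pair, since chance-level SCI is
$\approx \sqrt{p_i p_j}$). This displacement is inherent to the method and
is visible in the default simulation, where a weakly planted pair loses its
edge slot to the hypertension–dyslipidemia background pair. No additional
$\Phi > 0$ condition is imposed in step 3: $t > 1.96$ already forces
positivity.

**Ties** at the cut-off rank are broken by higher $c_{ij}$, then
lexicographic pair id, so exactly $e$ edges are returned deterministically.

## Network metrics

Networks are simple, weighted (SCI), undirected; the node set is the
cohort's retained-condition list, so conditions without significant edges
remain as isolated nodes and are counted (published node counts equal
retained-condition counts). Density is $E / \binom{n}{2}$ and average
degree $2E/n$; both are asserted as self-consistency identities on every
run, together with the handshake identities for degree and weighted degree.

**Harmonic centrality** of node $v$ is
$\frac{1}{n-1}\sum_{u \ne v} 1/d(u,v)$ with $1/\infty = 0$, over
*unweighted hop-count* shortest paths. The $(n-1)$ normalization keeps
values in $[0,1]$ and is our documented assumption; published values below
1 are consistent with a normalized convention but the exact choice is not
stated in the source material. SCI weights deliberately do not enter path
lengths — centrality here is a purely topological proximity notion — and
influence only weighted degree and PageRank.

**PageRank** (damping 0.85, configurable) treats each undirected edge as
two directed arcs with transition probability proportional to SCI weight;
isolated nodes are dangling and redistribute uniformly. The implementation
is a power iteration run to an L1 change below $10^{-9}$; tests verify it
against both a dense 200-step power iteration over the explicit Google
matrix and `igraph::page_rank()`. Hubs are the top 10 by score, ties broken
lexicographically. Scores sum to 1 within $10^{-9}$ by construction.

**System aggregates** sum degree and weighted degree per ICD-10 chapter.

## Contrasts

`difference_network(A, B)` is a set difference on unordered pair identity
(A's significant edges absent from B's), keeping A's SCI weights. The
subgroup-unique report lists pairs whose membership count across the four
significant edge sets is exactly one — uniqueness is evaluated *after* the
cut-off, not on raw co-occurrence, matching the "unique and significant"
notion. The identity "unique pairs of A = intersection over B of
difference(A, B)" is asserted in tests. A condition dropped by one
cohort's prevalence filter simply contributes no edges there; no special
casing.

## The synthetic cohort generator

The generator emulates a two-cohort hospital-linkage extract so the whole
pipeline is testable without restricted data:

- **Demographics.** 18,971 patients per cohort by default, 49.4% female,
  index ages on the four bands 10–17 / 18–39 / 40–59 / 60–79 with weights
  3.6 / 27.7 / 32.9 / 35.9%; the T2DM cohort *copies* the T1DM (sex, index
  age) multiset so exact matching succeeds in full by default
  (`unmatched_fraction` injects mismatched strata to exercise failure
  paths).
- **Calendar.** Index dates uniform over 2014-01-01 … 2023-12-31; observed
  follow-up log-normal per cohort, fitted from group medians and IQRs
  (T1DM 3.80 (1.36, 7.13); T2DM 8.28 (4.85, 10.34) years); last visit =
  index date + follow-up.
- **Laboratories.** Per type × sex: normal for HbA1c (IFCC mmol/mol), TC,
  LDL-C, HDL-C (means/SDs as printed in the matched-cohort summaries the
  defaults are calibrated to); log-normal for TG, ALT, AST, ALP, GGT, UA,
  UMA, with meanlog/sdlog fitted from the printed median and quartiles.
- **Conditions.** Independent Bernoulli indicators at subgroup-specific
  marginals (baseline × female ratio × T2DM ratio). The default
  22-condition catalog is *illustrative* — grouped-condition dictionaries
  are institution specific — and user-replaceable.
- **Planted pairs.** For each planted pair we compute the exact 2×2 joint
  cell matching the configured odds ratio while preserving both marginals
  (the closed-form Plackett solution — the same fixed point iterative
  proportional fitting of the 2×2 converges to) and re-draw `code_j`
  conditional on `code_i`. Conditioning on `code_i` leaves it untouched, so
  chained pairs sharing a condition (gastritis in
  nephropathy–gastritis and gastritis–asthma) compose correctly; the
  validator rejects configurations where a code would recur as `code_j`
  within a subgroup, which would destroy an earlier pair's association.
- **Seeding.** One root seed spawns a deterministic substream per stage,
  per condition, per planted pair and per lab, so adding a condition to a
  config does not perturb unrelated draws, and identical configs are
  bit-identical.

**What it does not emulate — and what passing tests therefore show.**
Background conditions are mutually independent, whereas real EHR conditions
are broadly positively correlated (age and utilization drive co-occurrence
across the board). Synthetic networks are therefore far sparser than real
ones — with independent backgrounds only planted pairs can clear the
$t$-screen at scale — and the published per-subgroup edge counts (78–92) and
densities are *not* reproduced by simulation; they are checked instead as
internal-consistency identities from the printed node/edge counts.
Follow-up is drawn log-normal without the administrative censoring a fixed
database window imposes, so the synthetic upper quartile of the
long-follow-up cohort exceeds the printed one and the log-scale follow-up
SMD overshoots the printed value (≈ −0.8 vs −0.59); the realized *medians*
match the calibration targets. Visit-level utilization, code hierarchies
below the grouped-condition level, mortality and temporality are out of
scope. Passing tests demonstrate that the *pipeline* computes the method
correctly and recovers known planted structure — not that the synthetic
cohort reproduces any real cohort's network.

## Descriptive statistics

Approximately normal variables are summarised as mean ± SD, skewed ones as
median (Q1, Q3) with linear-interpolation quantiles, categorical ones as
counts (%). The standardized mean difference uses the two-group
average-variance pooled SD,
$\mathrm{SMD} = (\bar{x}_A - \bar{x}_B) / \sqrt{(s_A^2 + s_B^2)/2}$ — the
standard matched-cohort convention; the source material names the SMD but
not the formula, so this is a documented assumption. Skewed variables are
log-transformed first (natural log; $\log(x+1)$ when either group contains
zeros; negative values are an error). Multi-category variables (age bands)
report one binary SMD per level rather than a pooled Mahalanobis-style
statistic, mirroring row-per-band presentation. Equal proportions return
SMD 0 under a guarded division (including degenerate 0/0 and 1/1); equal
means with zero pooled SD return 0, unequal means with zero pooled SD
return signed infinity. HbA1c is generated and analysed on the IFCC scale
(mmol/mol); the NGSP% display conversion ($0.09148 \cdot \mathrm{IFCC} +
2.152$) is a display-layer helper only. Rows missing a lab are dropped per
variable with the count recorded.

## Validation design and problem sizes

The suite runs at sizes chosen to keep the full check fast while leaving
no statistical ambiguity:

- **Oracle equivalence:** 100 random fixtures (≤ 50 patients, ≤ 8
  conditions) comparing counts, SCI, $\Phi$ (vs `cor()`), $t$, the full
  cut-off and edge sets against independent brute-force enumeration.
- **Planted recovery:** 20 replicates of a calibration scenario — 10,000
  patients per cohort (~5,000 per subgroup), 12 background conditions at
  5–15% prevalence, one subgroup-unique planted pair per subgroup with
  odds ratio 8 and 10% margins, no planted lab shift. The settings come
  from an explicit power computation: the planted joint cell is
  $p_{11} \approx 0.037$, giving expected SCI ≈ 0.37 against ≤ 0.13 for
  the strongest background pair and expected $t \approx 4.3$ (sampling SD
  ≈ 0.25), so the 1.96 screen and the top-$e$ ranking are both cleared
  with wide margins while remaining far from saturation. Acceptance asks
  for ≥ 90% of replicates recovering all planted pairs, ≥ 90% surfacing
  them as subgroup-unique, and ≥ 95% keeping every null lab |SMD| < 0.10.
- **Invariants:** handshake identities, PageRank normalization to
  $1 \pm 10^{-9}$, harmonic centrality in $[0,1]$, SCI/Φ ranges, symmetry
  and cohort-duplication invariance, matching exactness, the inclusive 1%
  boundary.
- **Determinism:** identical config + seed ⇒ byte-identical output files.

## Known limitations

Edges encode co-occurrence only — no temporality, directionality or
causality. The $c_{ij}$-based $t$ makes the screen insensitive to cohort
size beyond its effect on joint counts; with the conventional $N-2$ form
the same data would yield far more significant pairs. The default catalog
and its prevalences are illustrative stand-ins for an unpublished
institution-specific grouping dictionary. The displacement behaviour of
the top-$e$ SCI ranking (see above) means edge identity near the cut-off
is sensitive to the background prevalence structure.
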