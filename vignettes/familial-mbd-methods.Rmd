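---
title: "Methods: segregation analysis of familial malignant blood disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segregation analysis of familial malignant blood disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famMBD)
```

## The problem

Familial clustering of malignant blood disorders (MBD) — the leukemias,
lymphomas and myeloma — does not follow Mendelian ratios. Genealogical
series show asymmetries between paternal and maternal lines, sex-specific
parent–offspring combinations, a birth-order effect confined to particular
strata (male CLL in paternal lines), deviation of specific diagnosis
pairings from prevalence-based expectation (co- and contravariation), and
anticipation (more disease, earlier onset, in later generations). These are
the signatures expected of parental genomic imprinting interacting with
feto-maternal microchimerism: transmission that depends on the sex of the
transmitting parent and on the child's position in the sibship.

famMBD implements the full analysis chain for such material, plus a
generator of synthetic pedigrees with exactly these mechanisms, so that
every statistic can be checked against data whose true parameters are
known. Raw registry pedigrees of this kind are not publicly sharable;
published per-table counts are therefore packaged as fixtures
(`fixture_tables()`) and everything else is validated on simulated data.

## The pair machinery

**Proband–relative enumeration.** Every affected member is proband crude
(Pc) in turn. Its affected relatives (AR) are affected *ancestors* within
`max_generations` (default 5) whose connecting path holds at most
`max_healthy_intermediates` (default 5) unaffected members strictly between
Pc and AR. Both caps are counted on the shortest ancestral path per first
edge; affected intermediates do not count against the healthy cap (a
literal reading of "healthy members between"). One person may be AR to many
probands, so pair counts legitimately exceed patient counts. Raising either
cap can only add pairs (a property the tests exercise).

**Lineage.** A pair is PA when the first ancestral step from the Pc runs
through its father, MA through its mother. In a consanguineous kindred an
ancestor may be reachable through both parents. There is no canonical tie
rule in the field; we emit one pair per distinct first edge (one PA, one
MA), flag both as `consanguineous`, and signal a classed warning from
`classify_lineage()`. Double-listing with flags preserves the information a
sensitivity analysis needs; any stricter rule can be applied downstream by
filtering on the flag.

**Vertical pairs.** The reported pair table retains only vertical pairs
with generation gap ≤ 2 (parent–offspring, grandparent–grandchild). All
non-vertical relations (uncle/aunt–nephew, cousins, and by extension any
collateral relation) are treated as oblique and excluded; sibling
concordance ("horizontal") pairs are available separately through
`horizontal_pairs()` but never enter the table. A grandparent–grandchild
pair may have an unaffected intermediate generation; `healthy_intermediates`
is carried on every pair so both readings (allowing or forbidding the
skipped generation) can be reported.

## Statistics

**Prevalence and expectation.** Within-group prevalence is
`100 · n_d / n_group`, reported at one decimal with half-up rounding —
`round_half_up()` rounds 62.5 to 63, matching the reporting convention of
the cohort tables (R's default banker's rounding does not). The expected
AR count deliberately uses the one-decimal prevalence (8.7% of 121 =
10.53), because that is how the expectation is defined in this literature;
`exact_prevalence = TRUE` switches to the unrounded ratio. The expected sex
split follows the diagnosis's own case sex ratio, so male + female always
equals the total before display rounding.

**Co-/contravariation.** The test statistic is Pearson's chi-square over
the (male, female) OBS-vs-EXP cells with 2 degrees of freedom and no
continuity correction, the convention used with these tables; under
independent Poisson sex cells (equivalently, a Poisson total split
multinomially in the expected proportions) this is calibrated at the
nominal level, which the Monte-Carlo acceptance test verifies at 10,000
replicates. Two classifications are reported: `direction` (the sign of
OBS − EXP, always defined) and `call` (the direction gated at `p < alpha`,
default 0.05, otherwise `none`). They are kept separate because the
published significance thresholds for these cells are not reproducible
from the printed counts with any obvious 1- or 2-df Pearson layout; the
package reports its own documented chi-square rather than tuning to match,
and the direction alone reproduces every printed co/contravariation call.
No multiple-testing adjustment is applied (none is applied in the source
tradition). A zero expected sex cell is an error instructing the caller to
pool cells rather than a silent `Inf`.

**Haldane–Smith birth-order test.** Per sibship `j` (full sibs only: same
father and same mother; half-sibs form separate sibships, the only reading
under which the null placement is exchangeable), with size `s_j` and `m_j`
cases at ranks `r`: the contribution is `Σ r`, the null mean
`m_j (s_j + 1) / 2`, the null variance `m_j (s_j − m_j)(s_j + 1) / 12`
(sampling ranks without replacement). Totals are summed over sibships and
referred to a normal approximation; the 95% interval is
`mean ± 1.96 · sd`, and the decision is `late_excess` above the upper
bound, `early_excess` below the lower. Sibships with zero null variance —
singletons, or all sibs cases — contribute nothing and are excluded from
the informative count; an analysis with no informative sibship errors
rather than returning a vacuous result. The tests verify the moments
against exhaustive enumeration of every placement for all sibship sizes up
to 6 and the type-I rate (0.03–0.07 at α = 0.05) over 10,000 simulated
null datasets of 30 sibships.

Birth rank is stored explicitly (1-based within the full sibship). When it
is absent it is derived from birth year, ascending, ties broken by id
lexicographically, with a warning — the ranking needs a deterministic tie
rule and none is canonical.

**Wilcoxon control.** Per case, score = (older healthy sibs) − (younger
healthy sibs); a one-sample Wilcoxon signed-rank test against zero, zero
scores dropped per the standard convention. When every score is zero the
test is reported as undefined (`NA` with a note), not as p = 1.

**Anticipation.** A generation stratum is the member's depth: the maximum
parent-path length to any founder — the only operational definition that is
well defined in looped pedigrees (marrying-in spouses are founders at depth
0 and never affected in simulations, so they do not dilute the strata).
The onset trend is a two-sided Kendall rank correlation of onset age with
depth (robust to the non-normal, truncated onset distributions of registry
data), supplemented by a least-squares slope whose negation is reported as
`decline_per_generation` in years. If all onsets are equal the trend is 0
with p = 1 by construction; with fewer than two affected strata it is
undefined (with a warning). Familial-vs-registry prevalence comparisons are
per-diagnosis chi-square goodness-of-fit tests of the familial count
against the reference proportion.

## The generator

The imprinting-style model is deliberately a *two-state carrier process*
with sex-dependent transmission weights, not an allele-level simulation:
pair statistics constrain only the transmission weights, so an explicit
silencing/erasure cycle would add parameters no downstream statistic can
identify.

* **Transmission.** Each couple has at most one designated carrier. A
  carrier parent transmits to each child with base rate `transmit_rate`,
  tilted by sex of child: daughters receive with probability
  `2 · t · maternal_drive`, sons `2 · t · (1 − maternal_drive)`. Because a
  carrier child's sex is thus Bernoulli(`maternal_drive`), the sex of the
  transmitting parent in the *next* generation — and hence the PA/MA label
  of every vertical pair — is maternal with probability `maternal_drive`
  at every depth. `maternal_drive = 0.5` is the symmetric null;
  feasibility requires `2 t · max(drive, 1 − drive) ≤ 1`, checked before
  sampling. Non-carriers never have affected descendants through their
  line.
* **Diagnosis and penetrance.** Carriers draw a "destined" diagnosis from
  a prevalence mixture (default: the continental familial case mix) and
  become affected with probability `penetrance` (default 0.3, which under
  nuclear ascertainment reproduces a realized mean near the reported 2.7
  cases per family). The birth-order enhancement multiplies the penetrance
  *odds* by `beta^(rank − 1)`, by default only for male CLL carriers in
  paternal lines — the one stratum with a reported late-birth excess — and
  `beta = 1` together with `anticipation_delta = 0` recovers the null
  model exactly.
* **Onset.** `onset = onset_median − depth · anticipation_delta +
  N(0, onset_sd)`, truncated at zero; Gaussian noise (median 67 y, sd 10 y
  by default) is the simplest documented, seed-stable choice.
* **Modes.** Nuclear mode draws independent three-generation families and
  re-draws each until it has ≥ 2 affected (the ascertainment rule of a
  clinic-recruited series). Endemic mode grows one connected kindred over
  5 generations (default sibship mean 5 — a high-parity isolate — and
  transmission 0.85 so the susceptibility persists); children marry within
  the pedigree with probability `loop_rate`, producing the consanguinity
  loops that exercise the ambiguity machinery. The loop rate is a knob,
  not calibrated to any particular population.
* **Determinism.** `generate_pedigree()` requires a seed, restores the
  caller's RNG state, and identical seeds give identical pedigrees — the
  pipeline is a pure function of (input digest, configuration, seed).

What the generator does *not* emulate: demographic history (bottlenecks,
remarriage patterns), HLA haplotypes and microchimerism at the molecular
level, sporadic (non-carrier) cases, twins, missing or erroneous records,
and age-structured censoring. Passing tests therefore demonstrate that the
statistics recover the transmission structure they target under clean
conditions — not that registry data meet those conditions.

## Problem sizes used by the test suite

The suite favours many medium simulations over few large ones: null
calibrations pool 20–25 replicates of 20–30 families; drive recovery uses
batches of 400 families until at least 2,000 vertical pairs are collected
(the scale at which a ±3-point band on the maternal fraction is
meaningful given family-level clustering of lineage); anticipation
recovery uses 75 families (≈ 200 affected over three generations, putting
the ±2-year band at roughly two standard errors of the slope); the
birth-order power scenario uses 100 families, which yields on the order of
40 informative paternal-line male-CLL sibships per replicate. Both 10,000
replicate Monte-Carlo calibrations are vectorized closed forms of the same
statistics the package functions compute, with spot-check agreement
against the functions themselves.

## Known limitations

* Oblique relations are excluded wholesale; the package does not attempt
  the finer distinctions (great-uncle versus uncle) a registry analysis
  might make, and records `healthy_intermediates` so stricter filters can
  be applied afterwards.
* AR pools for observed-vs-expected analysis depend on the full pedigree;
  when only printed pool sizes exist (as for the endemic cohort), they
  must be supplied as fixtures rather than recomputed.
* The chi-square gate for co-/contravariation treats the sex cells as
  independent counts (2 df); other defensible layouts exist, which is
  precisely why `direction` is reported ungated alongside `call`.
* Members flagged `uncertain` in the input are excluded with severed
  parent links, without attempting to reconstruct uncertain positions.
* PED round-trips carry diagnosis, onset, birth order and birth year in a
  sidecar; a missing PED phenotype (0/−9) degrades to "unaffected" with a
  message, so the native CSV dialect is preferred for lossless storage.
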