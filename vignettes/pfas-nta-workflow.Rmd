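---
title: "Non-target PFAS screening: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-target PFAS screening: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasnta)
```

## The problem

Non-target analysis of negative-mode LC-QTOF data from biological extracts
yields on the order of 10^4 aligned features, of which only a handful are
per- and polyfluoroalkyl substances (PFASs). `pfasnta` implements a
case-control prioritization cascade that exploits three properties of
PFASs: they are reproducibly measurable (replicate filters), they are
contamination-specific (blank and case-control filters), and their
fluorinated backbones give them near-zero CF2-normalized Kendrick mass
defects and CF2-spaced homologous series (mass-defect filters and series
detection). What survives is annotated by exact mass, isotope pattern and
diagnostic MS/MS fragments, and graded on the PFAS adaptation of the
Schymanski identification-confidence scale (1a--5b).

## Exact-mass arithmetic

All mass computation is done on element-count formulas over
C, H, N, O, S, F, Cl, P, Na, K with monoisotopic masses pinned in
`element_table()` (quoted to >= 6 decimals, so 5-ppm comparisons at m/z 100
are not limited by the constants). Ion m/z always includes the electron
mass (0.000549 Da per negative charge); many tools omit it, and above
m/z ~110 the omission stays inside a 5 ppm window, but inclusion is the
documented contract here. Two ion conventions are supported:
`ion_mz(f, "ion")` for formulas written as the ion (e.g. `C9H5F13NO4S-`)
and `ion_mz(f, "deprotonated")` for neutral molecules measured as [M-H]^-.

```{r}
ion_mz("C9H5F13NO4S-", mode = "ion")       # sulfonamido-propanoate anion
ion_mz("C6HF13SO4", mode = "deprotonated") # O-PFHpS / PFHx-OS isomer pair
```

The first-isotope ratio `isotope_m1_ratio()` uses the single-substitution
closed form (sum of count x abundance ratio over 13C, 2H, 15N, 17O, 33S),
which agrees with a full convolution of per-atom isotope distributions to
10^-6 for formulas of the size handled here; full fine structure and M+2
patterns (Cl!) are out of scope, which is why the suspect-screening isotope
criterion only uses M+1. Ring-and-double-bond equivalents
(`rdb()` = C - (H+F+Cl)/2 + (N+P)/2 + 1) return half-integral values for
ionic compositions with a flag instead of an error, because RDB serves only
as a candidate plausibility screen.

## Kendrick mass defect

The CF2-normalized Kendrick mass is `KM = mz * 50 / 49.996806` and the
defect is `KMD = round(KM) - KM` (nearest integer, R's default
ties-to-even; the convention and rounding are fixed package-wide so the
same feature always gets the same KMD). With this sign convention PFAS
fall in a narrow band around zero -- the prioritization window is
[-0.15, 0.15], inclusive on both ends -- while hydrogen-rich metabolites
drift to strongly negative KMD as mass grows:

```{r}
kendrick(c(469.9736, 475.9310, 500.3000))
```

KMD is exactly invariant under shifts by whole CF2 units, which is the
property that makes homologous series horizontally adjacent in a KMD plot.

## The prioritization cascade

`prioritize()` applies five independent predicates in a fixed order and
records full per-filter provenance; the surviving set equals the
intersection of the individual pass sets, so the order only affects the
staged counts, not the outcome. Defaults (all configurable in
`pipeline_config()`):

| filter | rule | default |
|---|---|---|
| replicate RSD | present in every case injection, sd/mean x 100 strictly < threshold | 20 % |
| blank ratio | case mean strictly > factor x max blank intensity | 10x |
| RT window | inclusive bounds, minutes | 1--13 |
| KMD window | inclusive bounds, Da | -0.15..0.15 |
| case-control | log2 fold change strictly > threshold and Welch p strictly < threshold | 0.9, 0.05 |

Boundary conventions: windows are inclusive; criteria quoted with a strict
inequality (RSD "< 20 %", blank ">10x", fold change ">0.9", "p < 0.05")
are strict, so a feature at exactly 10x blank fails. The blank comparison
uses the *maximum* across blank injections (the conservative choice; the
mean is not exposed because the max dominates carryover risk), and a
feature absent from all blanks passes whenever its case mean is positive.
RSD is computed on raw intensities ("based on the mean intensity"), not on
logs. The 5000 cps detection floor applies at observation ingestion
(`align_observations()` drops weaker non-blank observations), not inside
the RSD filter. When a design has several case pools injected in
triplicate, the RSD rule is applied literally across all case injections;
the generator draws all case injections of a feature from one log-normal,
so the per-pool and pooled readings of the rule coincide on synthetic data
-- on real data with strong pool-to-pool biology a user may prefer to
filter per pool and should subset the design accordingly.

**Statistics.** The "log fold change" base is not fixed by vendor software
conventions; log2 is used (threshold 0.9 ~ 1.87-fold) and configurable.
Because contamination-specific features are near-absent in controls, the
selection is insensitive to the base. The test is Welch's unequal-variance
t-test on log2 intensities with Welch--Satterthwaite degrees of freedom,
computed on per-sample (pool) means so that biological samples, not
replicate injections, are the statistical units. Zeros are imputed at
`imputation_floor` (default 0.5) times the smallest positive intensity in
the table before the log transform, which keeps fold changes finite; when
both groups are constant the p-value degenerates to 1 (equal) or 0
(unequal). Raw p-values are used by default, mirroring common NTA practice
of p < 0.05 without correction; `p_adjust = "BH"` is available.

**Alignment** is greedy intensity-seeded clustering: observations sorted by
descending intensity (m/z tie-break) seed clusters; each observation joins
the nearest seed within 0.02 Da and 30 s or starts a new cluster. This is
deterministic, input-order independent, idempotent on consensus features,
and agrees with transitive-closure clustering whenever clusters are well
separated (>= 3 tolerances), which is the regime the detection floor
enforces in practice.

## Homologue series

`detect_series()` makes the visual KMD-plot reading algorithmic: candidate
edges connect features whose m/z difference is within `mz_tol` (0.01 Da)
per unit step of an integer number of repeat units and whose KMDs differ by
at most `2 * kmd_tol`; connected components are then pruned (worst KMD
offender first, ties broken by higher m/z) until every member sits within
`kmd_tol` (0.005 Da) of the component mean. The numeric tolerances are
declared assumptions -- no published values exist for calling features
"homologous" -- and were chosen so that an observed pair spaced 99.9917 Da
apart is linked to the theoretical C2F4 spacing of 99.9936 Da (1.9 mDa
apart) while random matrix pairs are not. RT consistency
(`series_rt_consistency()`) demands elution order follow homologue mass
(reversed-phase convention) with a configurable slack per unit, default 0
(equal RTs fail). Repeat-unit discovery is deliberately out of scope: the
unit is user-supplied (CF2 default; C2F4, CH2, C2H4O are common
alternatives).

## Annotation and confidence

The spectral-library **fit score** is the intensity-weighted fraction of
library peaks having a query peak within 0.01 Da, scaled to 0--100, so 100
means the library spectrum is fully contained in the unknown -- the
documented behaviour of vendor "Fit" scores, whose exact algorithms are
proprietary. Equivalence with any vendor score is not claimed; the >= 80
hit threshold is a calibration parameter. A library hit additionally needs
< 5 ppm precursor error, the match in >= 3 replicate spectra, and RT
consistency with the homologue series. Suspect screening needs < 5 ppm and,
when an observed M+1 ratio exists, < 5 % isotope-ratio difference; the
isotope criterion is skipped (not failed) when no observed ratio is
available, since data-independent acquisition features often lack one.

The built-in `fragment_rules()` encode the class-diagnostic logic:
sulfonates show SO3^- (79.9574) and FSO3^-; sulfonamides show NO2S^-
(77.9655); sulfonamido-propanoates add the C3H4O2 neutral loss
(72.0211 Da); the N-methyl sulfonamide-SO2 class shows CH3NO2S^- (92.9890)
and CH3NO4S2^- with C6F13/C8F17 chain losses *and requires SO3^- to be
absent* -- absence requirements are honored as vetoes. Published fragment
tables occasionally carry inconsistent labels (an "SO3-" label on m/z
77.9655, which is the NO2S^- mass; a 397.9527 fragment labelled C6F13SO3NH
whose mass matches C6F13SO2NH^-; a 423.9629 fragment ~12 ppm from its
printed composition); the rule table keeps compositional masses and records
the discrepancies in comments rather than silently correcting either side.

`assign_confidence()` is a deterministic ladder over recorded evidence:
1a (library + reference-standard RT) > 1b (library MS/MS only) > 2a
(diagnostic fragments, unique reported structure) > 3a (positional isomer
candidates remain) > 3b (novel structure from fragmentation alone) > 4
(formula only) > 5a (suspect exact mass) > 5b (exact mass of interest).
One deliberate subtlety: a suspect match whose isomer candidates cannot be
distinguished degrades to 5b, not 5a -- ambiguity always downgrades, and
removing evidence can never raise a level. Levels 2b and 4 are included for
completeness of the scale even though typical screening outcomes
concentrate on 1a/1b/2a/3a/3b/5b.

## The synthetic-data generator

`generate_dataset()` emulates the structure of a pooled case-control
study: 4 case pools and 4 control pools injected in triplicate plus
procedural blanks, ~20 planted PFAS features across six classes (PFSA
C4--C8, PFCA C8--C11, FASA C3/C4/C6/C8, Cl-PFSA C6--C8, FASA-PrA C6/C8,
MeFASA-SO2 C6/C8), 500 hydrogen-rich matrix features present in case and
control alike, and 30 blank-contamination features present everywhere.
Numeric choices and what they emulate:

* mass error: Gaussian in ppm, sigma = 2 ppm truncated at 5 ppm, matching
  instrument calibration kept below 2 ppm;
* replicate intensity noise: log-normal with log-SD 0.10 (~10 % RSD), a
  typical well-behaved LC-MS injection series; per-feature medians scatter
  log-normally (log-SD 0.5) around class medians of 0.8--2 x 10^5 cps;
* retention times increase by ~0.8 min per CF2 unit from class-specific
  intercepts, keeping all planted homologues inside the 1--13 min window
  with the reversed-phase elution order;
* matrix features are random CcHhNnOo compositions with c in 14--40 and
  H/C 1.3--2.1, whose deprotonated ions fall outside the +-0.15 KMD window
  with >= 90 % probability -- small, low-defect metabolites can and do leak
  into the window, which is precisely why KMD filtering alone is
  insufficient on biological matrices;
* control contamination: each planted PFAS appears in a control pool with
  probability 0.02 at 1 % of its case level;
* MS/MS: replicate DDA spectra from the class fragment templates with
  0.002 Da fragment jitter and 10 % intensity jitter.

Intensity distributions in real cattle blood are unpublished; the
log-normal settings are declared assumptions, not estimates. The generator
does **not** emulate chromatographic peak shapes, ionization suppression,
isotopologue peaks, in-source fragmentation, or correlated matrix
chemistry, so passing recovery tests demonstrates that the cascade logic
and tolerances are implemented coherently -- not that real serum data will
yield precision 1.0. The headline feature counts of real studies
(10^4 features in, dozens out) depend on raw instrument data and are not
reproduced at this scale; the test suite runs the full design
(548 aligned features, 27 injections) in ~2 s and uses 100 randomized
12-feature tables for the filter-equivalence property, sizes chosen to
keep the whole suite under half a minute.

## Degenerate inputs and numerical conventions

Empty observation tables align to empty feature sets (not an error); an
RSD over fewer than two injections is an error; Welch's test with zero
pooled variance returns p in {0, 1} by mean equality; formulas must be
non-empty over the supported element table, and unknown element symbols
are reported by name. All randomness flows through explicit integer seeds
(`set.seed` with Mersenne-Twister/Inversion pinned), and identical seeds
reproduce byte-identical datasets, reports and provenance hashes.

## Known limitations

Positive-mode ionization (cationic/zwitterionic PFASs), raw-data peak
picking, cross-batch RT alignment, quantification, in-silico fragmentation
and external database queries are out of scope. The confidence ladder
follows a fixed evidence precedence; borderline cases (e.g. a weak library
hit versus strong diagnostic fragments) resolve by that precedence rather
than expert judgment. The suspect-screening isotope criterion ignores M+2
isotopes, so it is weakly informative for chlorinated PFAS.
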