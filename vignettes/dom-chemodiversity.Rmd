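---
title: "Methods: DOM chemodiversity from FT-ICR-MS peak lists"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DOM chemodiversity from FT-ICR-MS peak lists}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domforge)
```

## The problem

Soil dissolved organic matter (DOM) is a mixture of thousands of organic
compounds whose composition shifts under land-use pressure such as
continuous monoculture cropping.  Ultrahigh-resolution mass spectrometry
(FT-ICR-MS) resolves this mixture into exact masses precise enough that
each peak can be mapped to a unique elemental formula
C~c~H~h~O~o~N~n~S~s~.  Downstream, the chemistry lives entirely at the
formula level: formulas are binned into biochemical compound classes by
their H/C and O/C ratios (the van Krevelen plane), into CHO / CHON /
CHOS / CHONS element groups by heteroatom content, and compared between
conditions as *sets* — a formula present only in the earlier condition
was *degraded*, one present in both *remained*, one present only in the
later condition was *produced*.  Finally, Spearman rank correlations
link DOM composition, soil chemistry and bacterial genera into a signed
co-occurrence network.

This package implements that pipeline end to end, plus a fully seeded
synthetic-study generator with known ground truth, so that every stage
is testable without instrument data.

## Formula assignment

A measured negative-mode peak is a singly deprotonated ion, so its
neutral mass is $M = m/z + m_\mathrm{proton}$.  Candidate formulas are
all integer compositions with

* $|m_f - M| \le \mathrm{tol} \cdot 10^{-6} M$ (default 1 ppm — a 15 T
  instrument is routinely sub-ppm, and the generator's default mass
  error of 0.3 ppm matches that regime),
* N $\le$ 3, S $\le$ 1, H/C $<$ 2.4, O/C $<$ 1.2,
* integer, non-negative double-bond equivalents
  $\mathrm{DBE} = 1 + c - h/2 + n/2$ (the parity constraint rejects
  radical neutral compositions, the only electron-parity screen
  available without isotope data), and
* $h \le 2c + n + 2$ (valence feasibility; for CHNOS this is the same
  inequality as DBE $\ge 0$).

Internally the package enumerates the complete valid formula space once
per parameter set (about 566,000 formulas under the defaults), sorts it
by exact mass and assigns peaks by binary search; the test suite checks
this against an independent oracle that solves the integer-H window per
(C, O, N, S) cell.  Element bounds (C $\le$ 60, H $\le$ 122, O $\le$ 40
by default) cover every formula below 1,000 Da with margin and are
configurable.

Among the candidates the one with the smallest absolute mass error is
selected; exact ties prefer fewer heteroatoms, then lower DBE, then
lexicographic element counts, so assignment is fully deterministic.
Unassigned peaks are kept with `NA` formulas so assignment rates stay
reportable.

**Known limitation — high-mass ambiguity.**  Above roughly 600 Da the
valid CHNOS space is dense enough that a second valid formula often
lies within 1 ppm of the true one.  With 0.3 ppm mass error the true
formula is then *always in the candidate set*, but the selected
formula is exact in only $\approx$ 85–95 % of cases at 600–1,000 Da
(it is essentially 100 % below 500 Da).  This is an
information-theoretic limit of mass-only assignment, not a tuning
issue; real instruments break such ties with isotope fine structure or
homologous-series logic, which are out of scope here.  The
`n_candidates` column lets users quantify and, if desired, filter
ambiguous assignments.  Composition percentages derived from assigned
(rather than true) formulas consequently carry a small extra bias of
up to a few points in the high-mass classes.

## Van Krevelen classification

The seven classes and their O/C x H/C boxes are: lipids (0–0.3,
1.5–2.0), aliphatic/proteins (0.3–0.67, 1.5–2.2), lignin/CRAM-like
(0.1–0.67, 0.7–1.5), carbohydrates (0.67–1.2, 1.5–2.3), unsaturated
hydrocarbons (0–0.1, 0.5–1.5), condensed aromatics (0–0.67, 0.1–0.7)
and tannins (0.67–1.2, 0.5–1.5).  Two conventions were genuinely open
and are fixed as follows:

* **Interval convention.**  Every box is half-open, $[$low, high$)$, on
  both axes.  Shared edges (O/C = 0.3 between lipids and
  aliphatic/proteins, H/C = 1.5 between lignin and lipids, ...) then
  belong to exactly one box, so classification is total and unique.  A
  formula with H/C exactly 2.3 (or O/C exactly 1.2) falls outside all
  boxes and is reported `unclassified`; the assignment screens H/C <
  2.4 and O/C < 1.2 make this rare.
* **Overlap precedence.**  The printed boxes overlap (unsaturated
  hydrocarbons and condensed aromatics share O/C < 0.1, H/C 0.5–0.7).
  Rows are applied in table order, first match wins, with the default
  order the conventional listing order; `classify_formula()` accepts a
  reordered table for users who prefer the other convention.

Formulas with O = 0 are classifiable (boxes with a zero O/C floor
include them), consistent with the low-O/C products the pipeline is
meant to surface.

## Composition, comparison, Venn

All accounting uses set semantics on the exact (C, H, O, N, S) tuple —
structural isomers are indistinguishable at the formula level, so
duplicated formulas within a sample count once.  Reported percentages
are rounded only at write time (2 d.p. for compositions and Venn
partitions, 1 d.p. for the degraded/remaining/produced split), with
half-away-from-zero rounding; full precision is retained internally.
Replicates of a condition are pooled by union before the two-condition
comparison; per-class rows report the D/R/P split within the pooled
membership of that class.

## Network inference

Spearman's rho is the Pearson correlation of average ranks.  The
two-sided p-value uses the exact full-permutation null for n $\le$ 9
(which, unlike classical tables, is valid under ties) and the t
approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ otherwise; the study
design (4 conditions x 3 replicates = 12 samples) lands in the
t regime.  Edges with p < 0.05 are kept and signed; no multiple-testing
correction is applied by default, matching common co-occurrence
practice of thresholding raw p-values, and a Benjamini–Hochberg flag is
available for stricter control.  Constant features are skipped with a
warning rather than erroring, and all samples (not condition means) are
the default correlation unit — condition means with n = 4 would leave
almost no power and can be emulated by passing an aggregated matrix.

## The synthetic generator

`generate_study()` emulates a 4-condition x 3-replicate continuous
cropping study, 5,000 unique formulas per sample:

* **Class mixtures** per condition interpolate linearly between the
  emulated endpoint trends — tannins 18.13 → 13.95 %,
  aliphatic/proteins 2.73 → 8.85 %, lignin/CRAM 56.83 → 53.20 % — with
  the residual shared so that condensed aromatics shrink and the
  high-H/C classes grow late.  Element-group mixtures interpolate CHON
  52.24 → 46.10 %, CHOS 5.81 → 11.10 %, CHONS 5.51 → 8.14 %.
* **Formula draws** rejection-sample integer compositions strictly
  inside the target class box (margin 0.01 on both ratios, avoiding
  edge ambiguity), with heteroatom counts fixed by the drawn group, and
  re-classify-checked, so the class label is exact by construction.
  Per-sample class counts are multinomial, which makes mixture recovery
  a clean binomial-error problem: at 5,000 formulas/sample and 3
  replicates the per-class standard error is about 0.4 points.
* **Peaks** are the \[M-H\]^-^ m/z of each formula perturbed by
  Gaussian error (s.d. 0.3 ppm), log-normal intensities, S/N mostly
  above 4 with a 5 % low-S/N fraction, plus 5 % noise peaks placed
  rejecting any m/z within 2 ppm of a valid formula mass — so
  "unassignable" has unambiguous truth.
* **Chemistry** variables follow per-condition means plus Gaussian
  noise: TC, TN, OM decreasing, C/N rising late, DOC V-shaped, pH flat.
* **Genus couplings** are planted through a Gaussian copula: the
  normal scores of the realised feature are mixed with independent
  noise at $\rho_z = 2\sin(\pi\rho_s/6)$, which makes the *rank*
  correlation equal to the target by construction (Spearman's rho is
  copula-determined).  Defaults plant four couplings at $|\rho_s|$
  0.9–0.95 against aliphatic/proteins, CHOS, TN and tannins, alongside
  uncoupled log-normal genera.

What the generator does **not** emulate: intensity structure across
classes (compositions are count-based, as in the emulated study),
isotopologues, inter-formula correlation within a sample, compositional
closure of genus tables (abundances are left unnormalised so planted
rank correlations stay exact), and realistic between-condition formula
overlap.  On that last point: conditions draw formulas independently
from a very large space, so the *remaining* fraction between the end
conditions is small (roughly 10 %) rather than the ~50 % a real
resampled soil would show; the D/R/P machinery is exercised, but its
percentages are not field-realistic.  Passing tests therefore show
correctness of the arithmetic and recovery of planted parameters, not
that real soils behave this way.

## Problem sizes and determinism

The test suite and the acceptance script run the default scenario
(12 samples x 5,000 formulas) for mixture recovery across 50 seeds,
planted-edge recovery across 100–200 replicate studies, null
calibration on 100 x 105 independent pairs, and oracle equivalence of
the enumerator on 500 random masses — sizes chosen so each property is
measured at 3+ sigma while a full run stays in minutes on one core.
Every stochastic step flows from a single integer seed;
`run_pipeline()` re-run with the same seed is byte-identical, including
the GraphML export and the run log (which deliberately contains no
timestamps).

## A worked example

```{r, eval = FALSE}
cfg <- scenario_config(seed = 1)
res <- run_pipeline(cfg, out_dir = "dom_run")
res$venn_pct
res$comparison
head(res$network$edges)
```
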