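---
title: "Hydrogen regulation of gut butyrogen fermentation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hydrogen regulation of gut butyrogen fermentation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(butyrogen)
```

## The scientific problem

Butyrate-producing gut bacteria (butyrogens) such as *Roseburia
intestinalis*, *Eubacterium rectale* and *Faecalibacterium prausnitzii*
ferment carbohydrates through a branched network that can yield butyrate,
acetate, lactate, formate, CO2 and H2 in varying proportions.  The branch
choice is not free: glycolysis reduces 2 NAD+ per glucose, and every
feasible fermentation must reoxidize that NADH.  Disposal onto protons
(making H2 via ferredoxin hydrogenase) becomes thermodynamically costly as
ambient H2 accumulates, so high dissolved H2 is expected to push flux away
from acetate + H2 and toward the reduced organic products butyrate, lactate
and formate.  Hydrogen-consuming microbes — above all the methanogen
*Methanobrevibacter smithii* — lower dissolved H2 and are therefore expected
to have the opposite effect.  This package implements the quantitative
scaffolding of that argument: the redox-balanced stoichiometry, the Gibbs
energy dependence on H2 partial pressure, the carbon-share accounting used
for culture endpoint data, and the breath-gas pipeline that classifies human
subjects by gut methanogenesis, plus simulators that generate data with
exactly the structure these analyses assume.

## The balanced fermentation family

With glucose fixed at -1 and both pyruvate carbons decarboxylated by the
oxidative route (CO2 = 2; no lactate or formate), elemental and charge
balance leave a one-parameter family indexed by the butyrate yield
$b \in [0, 2]$:

$$\mathrm{glucose} \rightarrow b\,\mathrm{butyrate}^- + (2-2b)\,\mathrm{acetate}^-
+ (4-2b)\,\mathrm{H_2} + 2\,\mathrm{CO_2} + (2b-2)\,\mathrm{H_2O} + (2-b)\,\mathrm{H^+}$$

`build_balance_family()` does not hard-code these coefficients: it fixes
glucose, butyrate and CO2 and solves the remaining coefficients from the
C/H/O/charge matrix; the closed form above is kept only as an independent
oracle in the tests.  The electron (degree-of-reduction) balance, taken
relative to the CO2/H2O/H+ reference ($\gamma = 4C + H - 2O - z$), closes
automatically because it is a linear combination of the element and charge
rows — `balance_check()` nevertheless verifies it, with residuals counted
as zero below 1e-9 after the linear solve.

Two consequences anchor the analyses:

* acetate changes from net product to net substrate exactly at
  $b = 1$ (the CoA transferase consumes one free acetate per butyrate
  released);
* the H2 yield $4 - 2b$ shrinks as butyrate grows, which is the entire
  thermodynamic story below.

## The flux model

`solve_fluxes()` distributes the family over the actual enzyme network.
Its three branch fractions are the lactate fraction $\lambda$ (pyruvate to
LDH), the PFL fraction $\varphi$ of the remaining pyruvate (the rest goes
through PFOR, reducing one ferredoxin pair each), and the butyrate fraction
$\beta$ of acetyl-CoA.  Bookkeeping per butyrate: 2 acetyl-CoA condensed,
1 NADH reoxidized by Bhbd, 2 NADH consumed by the electron-bifurcating
Bcd-Etf which returns 1 reduced ferredoxin pair, and a CoA-transferase
step that consumes one free acetate and recycles one acetyl-CoA to acetate
kinase.  The Rnf flux is solved to close the NADH balance, the hydrogenase
flux to close the ferredoxin balance; one can show the hydrogenase flux is
then never negative, so the only possible failure is an NADH surplus.

Design choices here were genuinely open:

* **Rnf ATP stoichiometry.**  Chemiosmotic energy conservation by Rnf is
  established, but its ATP-per-ferredoxin ratio is organism-dependent.  The
  default is $\eta = 0.5$ ATP per reduced-ferredoxin pair (2 translocated
  ions per pair, 4 per ATP), a mid-range literature value; it is an explicit
  `branch_params()` field and every $\eta$-dependent output records it.
* **NADH surplus handling.**  When $\lambda$ and $\beta$ are both small the
  network has no NADH sink (roughly $\lambda = 0$, $\beta < 2/3$).  The
  canonical network names only a ferredoxin hydrogenase, so by default the
  package reports an explicit infeasibility naming the violated balance
  rather than inventing a route.  Setting `allow_nadh_to_h2 = TRUE` enables
  a generic (confurcating-hydrogenase-like) NADH-to-H2 route for users who
  want the full family reachable; the simulators use it for closure.
  Whether the often-drawn "equal split" representative case closes through
  Rnf alone is exactly this question, and the package answers it by
  reporting the infeasibility instead of guessing.
* **Butyrate counting.**  Butyrate is counted per butyryl-CoA formed and
  the transferase's acetate-in/acetyl-CoA-out cycle is modeled explicitly,
  so the acetate-kinase credit for recycled acetyl-CoA is visible in the
  flux vector rather than folded into a net coefficient.

Useful fixed points: homolactate ($\lambda = 1$) reoxidizes everything with
zero hydrogenase flux and keeps only the 2 glycolytic ATP; pure butyrate
($\beta = 1$) gives ATP $= 3 + \eta$ and reproduces the $b = 1$ family
member coefficient-for-coefficient.  With the default $\eta$ the shift from
the butyrate/acetate fermentation to homolactate forgoes
$1.5/3.5 \approx 43\%$ of the ATP per glucose — the "roughly half" loss of
metabolic efficiency that makes these organisms facultative rather than
obligate syntrophs.

## Thermodynamics

`thermo_table()` carries standard formation energies from a Thauer-style
compilation (298.15 K, aqueous standard states) transformed to pH 7,
$\Delta_f G'^\circ = \Delta_f G^\circ + N_H\,RT\ln 10\cdot\mathrm{pH}$,
with the proton absorbed by the convention.  Sanity anchors reproduced by
the tests: glucose to 2 lactate $\approx -197$ kJ/mol, to butyrate + 2 CO2 +
2 H2 $\approx -264$ kJ/mol, to 2 acetate + 2 CO2 + 4 H2 $\approx -216$
kJ/mol.  The exact parameter set used for the published figure of this
kind lives in a supplement that is not reproduced here, so the shipped
values are documented defaults, not assertions about that figure.

Conventions, each of which was a real decision:

* **Gas standard states.**  H2, CO2 and CH4 enter the reaction quotient as
  partial pressures in atm against a 1 atm standard state — the natural
  convention when culture headspaces are reported in atm.  The
  physiologically relevant quantity is dissolved H2;
  `henry_dissolved_h2()` converts (7.8e-4 mol/L/atm at 298.15 K, van 't
  Hoff factor 500 K, about 0.73 mM/atm at 310 K) but is deliberately not
  the default evaluation path.
* **Temperature.**  Conditions default to 310.15 K while the formation
  energies stay at their 298.15 K reference without enthalpy correction;
  only the $RT\ln Q$ term uses the working temperature.  This is flagged
  here rather than hidden: no defensible reaction-by-reaction enthalpy set
  exists for these species at this precision.
* **pH.**  Fixed at 7 in the transformed convention unless overridden in
  `fermentation_conditions()`; off-reference pH shifts each species by
  $N_H\,RT\ln 10\,(\mathrm{pH}-7)$.
* **Defaults for "representative physiological conditions":** glucose
  10 mM, acetate 60 mM, butyrate 20 mM, lactate and formate 1 mM, 0.2 atm
  CO2 — literature-typical colonic/culture values, configurable.

For the family, $\partial \Delta G / \partial \ln p_{\mathrm{H_2}} =
(4-2b)RT$ exactly, so the $b = 2$ curve is flat and low-$b$ curves climb
steepest: past a crossing pressure the high-butyrate balances become the
more exergonic ones.  `sweep_h2()` tabulates $\Delta G(b, p_{\mathrm{H_2}})$
and annotates each point with the largest $n$ satisfying
$\Delta G \le -n \cdot 70$ kJ/mol, the conventional cost of ADP
phosphorylation; a zero H2 pressure against a nonzero H2 coefficient is an
explicit "unboundedly favorable" error rather than $-\infty$.

```{r sweep, fig.width = 6, fig.height = 4, eval = FALSE}
plot(sweep_h2())
```

## Carbon-share accounting

Culture endpoint data need a metric that does not hide the acetate nuance:
even when acetate is consumed net, acetyl-CoA still flows to acetate kinase
and earns ATP.  `monoculture_shares()` therefore sets a theoretical acetate
consumption equal to the butyrate produced, counts total fermented carbon
as $6\,\Delta\mathrm{glucose} + 2\,\Delta\mathrm{acetate_{theoretical}}$,
reconstructs total acetate produced as theoretical consumption plus the
measured endpoint-minus-blank change, and expresses each product as percent
of total fermented carbon.  Assumptions made explicit:

* constant culture volume (concentrations stand in for moles); gas-phase
  CO2 and H2 are not part of the carbon shares;
* butyrate, lactate and formate are absent from the medium, so small
  negative measured productions are instrument noise and are clipped to 0
  with a warning — but a *negative total acetate produced* violates the
  accounting's core assumption and is flagged, never clipped;
* one blank per record; whether blanks were replicated or batch-averaged
  upstream is the caller's affair, and the schema deliberately does not
  guess;
* zero glucose consumption makes the metric undefined (error), not zero.

For multi-species communities the per-strain attribution is not
identifiable and `community_yields()` falls back to moles of product change
per mole of substrate (glucose + fructose) consumed.  Group contrasts use
two-sided pooled-variance Student's t-tests per product with
0.05/0.01/0.001 star coding and no multiple-testing correction — matching
the per-product reporting convention of the experimental literature this
mirrors, and stated here so nobody mistakes the stars for family-wise
claims.

## Cohort pipeline

The human-cohort path is: normalize breath gases to a nominal 3.5% CO2
(`normalize_breath`); exclude, per metric across all samples of that
metric, values beyond 3 interquartile ranges outside the quartiles
(`tukey_exclude`); classify each subject-period as methanogenic when any
corrected CH4 reading strictly exceeds 4 ppm (`classify_methanogenic`);
average retained samples per subject and period
(`subject_period_means`); and compare MG with non-MG subjects by two-sided
two-sample t-tests (`compare_mg_groups`), with support for explicitly
excluding a flagged extreme observation.

Decisions worth recording:

* **Quartile convention.**  "Tukey's fences" does not pin a quantile
  estimator; the package uses linear interpolation (`stats::quantile`
  type 7, the common statistical default) and exposes `type`.
* **Order of operations.**  Fences are computed metric-wide before
  per-subject averaging, since the exclusion rule is defined per metabolite
  or gas, not per subject.
* **Baseline correction.**  Semesters with a known ~1 ppm instrument
  baseline get that baseline subtracted (floored at 0, negative gas being
  non-physical) before classification; the semester list is a parameter,
  not a heuristic.
* **Strict threshold.**  A reading of exactly 4 ppm is non-MG ("over
  4 ppm"), and classification is per period, so a subject can be MG during
  supplementation and non-MG before.
* **Paired versus unpaired.**  Published before/during gas contrasts of
  this kind do not always name the test; `before_during_contrast()`
  exposes both and reports which was used.

With fewer than 4 values the quartiles are too poorly defined to fence;
`tukey_exclude` then warns and keeps everything rather than fabricating
fences from 2-3 points.

## Synthetic data: what it emulates and what it does not

`gen_cultures()` emulates monoculture endpoint experiments: a handful of
biological replicates per strain and atmosphere, a glucose-defined medium
with abundant acetate and no butyrate/lactate/formate, and product shifts
under high H2 or CO.  Strain profiles are parameterised by target butyrate,
lactate and formate yields; the dependent acetate/H2/CO2 coefficients are
closed through the flux model, so every pre-noise record is elementally
balanced by construction.  The three default profiles encode the qualitative
response patterns seen in the well-studied butyrogens — one diverting
reducing power to butyrate and formate under H2, one mainly to lactate, and
a hydrogenase-free strain with no response at all (its all-PFL, all-butyrate
baseline emits no H2) — with *illustrative* effect sizes, since the
underlying bar heights are not printed anywhere reusable.  Noise is
multiplicative log-normal (HPLC error scales roughly with signal;
mean-corrected so the expectation is unbiased), switchable to additive
Gaussian.

`gen_cohort()` emulates a supplement cohort with a methanogenic
subpopulation: per-subject means (between-subject SD) plus per-sample noise
(within-subject SD), periods before and during supplementation, MG deficits
in breath H2 and fecal butyrate applied *only during* — the before period is
a true null.  Defaults: 40 subjects, half methanogenic, 3 breath and 3
fecal samples per subject-period; breath H2 8 ppm in both groups before and
20 (non-MG) versus 10 (MG) ppm during, between-SD 5 and within-SD 3; fecal
butyrate 8 µmol/g before and 12 versus 8 during, SDs 2.5/1.5; CH4 ~20 ppm
for MG and <4 for non-MG.  These are chosen as plausible cohort magnitudes
with effect sizes (Cohen's d roughly 1.5-1.9 on subject means) that a
20-per-group study would be adequately powered for.  The generator
guarantees truth-recoverability of the MG label (at least one CH4 draw
above threshold for MG subjects, none for non-MG) and back-computes raw gas
readings from the programmed normalized values so the CO2 normalization
step is genuinely exercised.  Injected outliers are upward spikes in units
of the within-subject SD, marked in a hidden `.outlier` column that readers
strip; a downward 10-SD excursion would clamp at zero and be undetectable,
so it is not generated.

What passing tests on these simulations do **not** show: real cultures have
growth-phase-dependent yields, CO2/bicarbonate exchange and volume changes;
real cohorts have skewed gas distributions, missing visits, within-subject
correlation across metrics and semester batch effects.  The simulators
validate the *pipeline logic* — normalization, fencing, classification,
averaging, testing — under the distributional assumptions the statistics
themselves make, nothing more.

## Numerical choices and problem sizes

Residual tolerance for "balanced" is 1e-9 absolute after the linear solve;
coefficients smaller than 1e-9 are treated as zero when printing and
classifying acetate sign.  Water/proton closure of flux-model net reactions
is an exact overdetermined solve whose residual is asserted, not assumed.
Property-style suites use fixed seeds with 200-1000 random cases
(balance grids at 0.01-0.05 spacing, 1000 random branch-parameter draws,
1000 random Tukey/t fixtures) and the cohort-recovery check uses 100
simulated cohorts of 40 subjects; these sizes give stable pass/fail
behavior at interactive runtimes and are stated here as the package's
standard verification conditions.

## Known limitations

* No ionic-strength (Debye-Hückel) corrections or pKa-resolved speciation;
  transformed energies are taken at the table's reference conditions.
* No kinetics: the flux model is stoichiometric, with no growth prediction
  or dynamic culture simulation, and the thermodynamics are equilibrium
  bookkeeping over fixed conditions.
* The accounting assumes the transferase route for butyrate release; for a
  butyrogen using butyrate kinase instead, theoretical acetate consumption
  would overstate acetate turnover.
* The cohort module implements plain two-group t-tests on subject-period
  means by design; it does not model repeated measures, semester effects or
  dose differences.
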