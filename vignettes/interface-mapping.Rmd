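---
title: "Mapping a peptide–VSD interface: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a peptide–VSD interface: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspmap)
```

## The experimental problem

A gating-modifier peptide binding a channel voltage-sensor domain (VSD) in a
micelle mimetic is a three-component system: the peptide binds the lipid
phase weakly and the protein partner more tightly, and both events leave
fingerprints in the peptide's ¹H-¹⁵N HSQC spectrum. Weak, fast-exchange
lipid binding moves peaks continuously (the observed shift is the
population-weighted average of free and bound); tighter binding on an
intermediate exchange timescale broadens a subset of peaks, in the extreme
beyond detection. `cspmap` turns peak lists from such titrations into
interface maps, binding constants, partition coefficients and docking
restraints, and ships a generator that fabricates all of these data with
known ground truth so that each stage can be checked by parameter recovery.

## Chemical-shift perturbation

For each assigned amide the combined shift change relative to the
zero-titrant reference is

$$\Delta\delta = \sqrt{\Delta\delta_H^2 + (\alpha\,\Delta\delta_N)^2},$$

with `alpha` = 0.15 by default — the conventional weighting that maps the
roughly 6–7-fold wider ¹⁵N dispersion onto the ¹H scale. Both `alpha` and
the functional form are arguments, not constants, because variants with an
extra normalisation factor (e.g. $\sqrt{1/2}$) circulate in the literature;
results only shift by a common scale factor, which the SD rule below absorbs.

**Significance.** The cutoff is one *population* standard deviation
(`ddof = 0`) of all endpoint $\Delta\delta$ values over backbone amides,
computed once with no iterative outlier exclusion, and a residue is
significant only on strict exceedance. Three consequences worth knowing:

* interface residues inflate the SD they are compared against, so the rule
  is conservative when the interface is large;
* if all values are equal and positive, the SD is 0 and everything is
  "significant" — a documented degenerate case, not an error;
* sidechain NH peaks (Trp indoles) are tracked through the pipeline but
  excluded from the SD pool, which is defined over backbone amides; fewer
  than three non-missing values is an error because an SD is meaningless.

## Exchange broadening

Spectra from different titration points differ in dilution and receiver
gain, so raw intensity ratios are not comparable. `broadening_profile()`
rescales each point so that the *median* intensity ratio over a
user-declared set of unaffected residues equals 1 — the median rather than
the mean so that one accidentally-perturbed "reference" residue does not
bias the correction. The extent of broadening is then
$B = 100\,(1 - I/I_0)$, clipped to $[0, 100]$, with lost peaks assigned
$B = 100$.

Severity tiers: `severe` = lost peak or $B \ge 90$ (threshold
configurable); `significant` = $B$ above 50 % of the mean broadening over
all scored residues; `moderate` = within (25 %, 50 %] of the mean; `none`
otherwise. The mean-relative tiers express that "unusually broadened" is
relative to the global exchange contribution in that titration, not an
absolute linewidth.

## The binding isotherm

`fit_kd()` fits the exact two-state quadratic model

$$\Delta_{obs} = \Delta_{max}\,
  \frac{(P + L + K_d) - \sqrt{(P + L + K_d)^2 - 4PL}}{2P}$$

by ordinary least squares. The exact form matters: at the design this
package targets (P = 20 µM observed species against 10–100 µM titrant) the
ligand-excess hyperbola is visibly biased. A hyperbolic variant is available
behind `model = "hyperbolic"` for comparison only.

Numerics: for fixed $K_d$ the optimal $\Delta_{max}$ is closed-form linear
least squares, so the fit profiles the RSS over a 200-point log-spaced
$K_d$ grid in $[10^{-3}, 10^{6}]$ µM and polishes the best bracket with
one-dimensional golden-section/parabolic optimisation (`stats::optimize`,
tol $10^{-12}$). This is deterministic, derivative-free, and cannot be
trapped away from the global profile minimum that the grid resolves.
$\Delta_{max}$ is boxed to $[0, 10\,\max|\Delta_{obs}|]$; fits that push
$K_d$ into its box edges are flagged `at_bound` rather than silently
returned. Standard errors come from the Gauss–Newton covariance with a
numerical Jacobian; they are honest about the main limitation of a 4-point
design — with 2 % noise, replicate simulations recover the median $K_d$
well but individual fits scatter widely (the test suite quantifies this at
200 replicates, requiring the median within 25 % of truth).

Weighting is unweighted OLS because per-point uncertainties are generally
not available for intensity series. Ternary competition (peptide
partitioning into empty micelles while also binding the protein) is *not*
inside the model; treat the fitted $K_d$ as an apparent constant at the
working micelle concentration.

## Membrane partitioning

The centrifugation assay measures free peptide left in the aqueous phase
after pelleting liposomes. Under the mole-fraction partition equilibrium,

$$\mathrm{bound/free} = K_p\,\frac{[\mathrm{lipid}]}{[\mathrm{W}]},
  \qquad [\mathrm{W}] = 55.3\ \mathrm{M},$$

which is linear in lipid concentration, so `fit_kp()` is exact closed-form
least squares through the origin — with this convention, $K_p \sim 10^5$
and millimolar lipid give order-unity bound/free ratios. Choices a user can
override: `water_conc` (55.3 M), and `leaflet_fraction` (default 1: total
lipid is counted as accessible; set 0.5 to count only the outer leaflet —
halving the accessible lipid exactly doubles the fitted $K_p$). HPLC areas
need no calibration curve: with a zero-lipid control the conversion to
concentration cancels in the ratios. Zero free-signal points would make the
ratio infinite; they are censored with a warning rather than fitted.
`percent_change()` keeps full precision and rounds only at the report
layer, since percent figures computed from rounded constants can differ by
a point or two from those computed from the unrounded fits.

## From evidence to docking restraints

`select_active_passive()` is deliberately mechanical, so the judgement
calls sit in its *inputs*: active = (severely broadened OR
mutagenesis-confirmed) AND surface-exposed; passive = other surface-exposed
residues with moderate/significant broadening or significant CSP. Surface
exposure is an input flag from any external accessibility computation —
this package stays geometry-light on purpose. A residue flagged
mutagenesis-confirmed but buried is contradictory evidence and is excluded
with a warning.

AIRs are emitted one `assign` statement per active residue against the
union of the partner's active ∪ passive residues, with distance fields
`2.0 2.0 0.0` (target/−/+, i.e. an effective 2.0 Å upper bound on the
ambiguous distance) — common docking-suite defaults, all overridable, and
documented in the bundled round-trip reader `parse_air_tbl()`. Restraint
accounting uses mutually exclusive sequence-range bins (intraresidue,
$|i-j|=1$, $2 \le |i-j| \le 4$, $|i-j| \ge 5$): the only reading under
which category counts partition a total. `paint_structure()` edits PDB
files at fixed columns 61–66 only, byte-preserving everything else, so a
painted file differs from its input in exactly the temperature factors of
the painted residues.

## What the generator emulates — and what it does not

`simulate_titration()` composes three ingredients per point: the bound
fraction from the same quadratic isotherm the fitter assumes; fast-exchange
population-average shifts $\delta = \delta_0 + f_b\,\Delta\delta_{max}$;
and an exchange-broadening intensity ratio
$\exp(-c\,f_b(1-f_b)\,\Delta\omega^2 / k_{ex})$ — the closed-form
fast-exchange line-broadening contribution, maximal near half-saturation —
with $c = 1$, $k_{ex} = 500\ \mathrm{s^{-1}}$ and a detection floor of 0.05
below which a peak is dropped from the list. It is *not* a Bloch–McConnell
lineshape simulation: there is no intermediate-exchange shift bias, no
differential relaxation, no overlap, no micelle ternary equilibrium, and
noise is i.i.d. Gaussian (additive 0.003 ppm on shifts, 2 % multiplicative
on intensities by default). Passing parameter-recovery tests on these data
therefore shows the analysis chain is self-consistent and correctly
implemented — not that real spectra satisfy its assumptions.

Default conditions mirror the two experimental arms: the protein arm at
P = 20 µM with titrant at 10/20/60/100 µM and a ground-truth
$K_d$ = 140 µM, broadening susceptibilities $\Delta\omega$ = 100 for the
severe pair (the R24 amide and W25 indole of the synthetic cast, which
vanish from 60 µM titrant onwards) and 45 for the moderate group; the lipid
arm at P = 30 µM against a micelle-like titrant at 2–20 mM with
$K_d$ = 5 mM (~80 % endpoint saturation) and six planted interface
residues with saturating combined shifts of 0.05–0.15 ppm. The rosters are
synthetic: residue names echo a spider-toxin cast so examples read
naturally, but the shifts and magnitudes are invented, order-of-magnitude
plausible values. Partition scenarios default to the assay design of 10 µM
peptide against 0.2–1.3 mM lipid.

## Problem sizes and runtime

All simulations are desk-scale by design: 34–36 peaks × 5 points per
titration, 4-point assays, 100-seed recovery sweeps, 200-replicate noise
studies and $10^3$–$10^4$-case property loops. The full test suite runs in
well under a minute on one CPU; `scripts/acceptance.R` in seconds.

## Known limitations

* Exchange-regime inference is out of scope: the user (or the detection
  floor of the generator) decides what "broadened out" means.
* The $K_d$ from broadening-selected intensity series is an apparent
  constant: intensity loss is not strictly proportional to bound fraction
  under exchange, which is why end-to-end recovery checks use shift series
  or directly generated isotherm responses.
* Active/passive selection encodes one published heuristic; other labs
  weight CSP vs broadening differently — the evidence-table interface makes
  that swap trivial but does not automate it.
* No support for NMR binary formats, peak picking or assignment transfer;
  peak lists are assumed assigned and consistent across points, and matching
  is strictly by label.
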