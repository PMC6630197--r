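---
title: "Methods: acid-base tension modelling and water-bridge analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acid-base tension modelling and water-bridge analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amphisurf)
```

## The tension model and its assumptions

An amphoteric phospholipid headgroup couples to the solution through two
independent equilibria: proton association with the phosphate
(`X^- + H+ -> XH`, constant $K_X$) and hydroxide association with the
ammonium group (`Y^+ + OH- -> YOH`, constant $K_Y$). The bilayer
interfacial tension is the speciation-weighted sum of four component
tensions,

$$\gamma(\mathrm{pH}) = \frac{\gamma^0_{X^-}}{1+K_X a_{H^+}}
 + \frac{\gamma^0_{XH}\,K_X a_{H^+}}{1+K_X a_{H^+}}
 + \frac{\gamma^0_{Y^+}}{1+K_Y a_{OH^-}}
 + \frac{\gamma^0_{YOH}\,K_Y a_{OH^-}}{1+K_Y a_{OH^-}}.$$

Assumptions made explicit by this package:

* **Ideal activities.** $a_{H^+} = 10^{-\mathrm{pH}}$ exactly and
  $a_{OH^-} = 10^{\mathrm{pH}-pK_w}$, with $pK_w = 14.0$ by default
  (configurable; no temperature correction).
* **Association-constant convention.** $K = 10^{pK}$ in 1/M. The DPPC
  exponents are 2.58 and 5.69, DPPE 2.42 and 5.98. These are *not*
  dissociation pKa values; `amphoteric_params()` documents this
  prominently because the sign convention is the easiest way to get the
  model silently wrong.
* **Two independent groups.** No electrostatic double layer, no
  surface-charge-density coupling between the groups, no lipids with a
  third titratable group (the serine lipid DPPS needs a three-group model
  and is deliberately out of scope; its tabulated values are reference
  data only).

### Identifiability and the fitted parameterization

Tension data determine only five combinations: the baseline
$B = \gamma^0_{X^-}+\gamma^0_{Y^+}$, the amplitudes
$A_X = \gamma^0_{XH}-\gamma^0_{X^-}$ and $A_Y = \gamma^0_{YOH}-\gamma^0_{Y^+}$,
and the two exponents. The split of $B$ into its two addends moves tension
between the two "1" weights of the sigmoids, which are indistinguishable at
every pH. `identifiable_params()` is therefore the fitting container, and
`as_amphoteric()` reconstructs a full parameter set only up to an arbitrary
(non-negative) split — the round trip preserves $\gamma(\mathrm{pH})$ to
machine precision, which the test suite asserts at 1e-12 relative.

### Isoelectric point

`compute_pI()` defaults to the arithmetic mean $(pK_X + pK_Y)/2$, which
reproduces the reference table exactly (DPPC 4.14, DPPE 4.20). A naive
charge-balance condition (equal anionic-phosphate and cationic-amine
concentrations) gives $(pK_w + pK_X - pK_Y)/2 = 5.45$ for DPPC instead;
both rules are implemented, the mean is normative because the reference
table is internally consistent only with it. Note a related model feature:
with the tabulated constants the *analytic maximum* of the tension curve
sits near the charge-balance value (pH 5.3–5.4), not at the mean-rule pI.
The two-group model cannot place its maximum at 4.14 with transitions at
2.58 and $14-5.69 = 8.31$ unless the amplitude ratio is extreme (~400:1),
so the package treats the mean-rule pI as a property of the *exponents*
and the curve maximum as a property of the *model*, and never conflates
the two.

### Display rounding

`(2.58 + 5.69)/2` is stored as 4.13499…98 in binary floating point, so
`round()` and `sprintf("%.2f")` give 4.13 where a scientific table prints
4.14. `round_half_up()` provides decimal ties-away-from-zero rounding and
is what the CLI and the acceptance report use for displayed pI values.

## Britton–Robinson buffer solver

`solve_pH()` finds the root of the charge balance
$[\mathrm{Na^+}] + [\mathrm{H^+}] = [\mathrm{OH^-}] + \sum_k C_k \bar{z}_k$
in pH $(0, 14)$, where $\bar{z}_k$ is the mean conjugate-base charge of
acid $k$ from its stepwise speciation and all analytical concentrations are
diluted by the added titrant volume. The default constants (25 °C,
thermodynamic scale) are acetic 4.756; phosphoric 2.148, 7.198, 12.35;
boric 9.237 (first step only); $pK_w$ 13.997. "80% acetic acid" in the
classic recipe refers to stock purity — only the 0.04 M final molarity
enters the charge balance.

**Why the Davies correction is the default.** With ideal activities this
recipe gives pH 1.86 / 3.50 / 7.19 at 0 / 20 / 50 mL of 0.2 M NaOH per
100 mL, missing the classic experimental checkpoints (1.81 / 3.29 / 6.80)
by up to +0.39: at ionic strengths of 0.03–0.1 M the mono- and especially
divalent anions (HPO$_4^{2-}$) are far from ideal, and a glass electrode
reports proton *activity*. Iterating single-ion Davies coefficients
$\log\gamma_z = -0.51 z^2 (\sqrt I/(1+\sqrt I) - 0.3 I)$ to
self-consistency with the ionic strength gives 1.874 / 3.439 / 6.897 — all
within the ±0.15 pH band that the remaining idealizations (no ion pairing,
single-parameter Davies form, 25 °C constants) warrant. `activity =
"ideal"` remains available and is what the brute-force grid-scan oracle in
the test suite checks against. The design intent had been a purely ideal
solver; the measured 0.2–0.4 pH misses made the activity correction a
necessity rather than a refinement, which is why this one deliberate
extension of scope exists.

`buffer_capacity()` is a plain finite-difference slope (central inside,
one-sided at the ends) and carries a response *kind* (`protons`,
`tension`, `friction`) so the same operation serves the classic
$\beta = \Delta H^+/\Delta\mathrm{pH}$ and the tension/friction analogues.

## Fitting tension curves

`fit_tension_curve()` minimizes the weighted residual sum of squares over
the five identifiable parameters with the three *linear* parameters
($B, A_X, A_Y$) profiled out by weighted least squares at each candidate
exponent pair (variable projection). The 2-D outer problem runs in
`nlminb` within bounds $[-2, 12]$ on both exponents — log-space keeps $K$
positive and conditions a problem that spans ten orders of magnitude —
from a data-driven start (transition guesses at the steepest observed
slopes on either side of the curve maximum) plus fixed fallbacks; the best
of the starts wins. Weights are $1/\sigma^2$ when per-point sigmas exist,
else 1. `nlminb`'s "singular convergence" code — routine in the flat
valley where the two exponents decouple — is verified by probing the
objective one step in each coordinate rather than trusted or rejected
blindly. Degenerate flat data produce a flagged baseline-only fit with a
warning, never an exception, and `fix_k` supports the mode where titration
already fixed the exponents and only the tensions are estimated.
`locate_maximum()` uses a 1e-3-pH grid scan plus golden-section
refinement; maxima of monotone curves land on interval endpoints.

Under the package's stated noise world (2% multiplicative, 30 points on
pH 1.5–9.5) the Monte-Carlo recovery study in the acceptance tests
measures RMSE($pK_X$) ≈ 0.08 over 100 seeded replicates, with the derived
pI within ±0.1 of the generating value in ≥ 95 of them.

## Young–Laplace conversion and molar surface energy

`young_laplace_gamma()` is the exact relation $\gamma = R\,\Delta p/2$ for
a spherical cap. `surface_energy()` converts a tension to J/mol via
$E = \gamma N_A a$ with the per-molecule area $a$ in Å². The shipped areas
(85.4 Å² DPPC, 77.0 Å² DPPE) are *derived calibration constants*: no
per-molecule area is published alongside the reference energies
(1800/1854 J/mol), so the areas were obtained once by inverting
$a = E/(N_A\gamma_{max})$ and are user-overridable.

## Synthetic tension fixtures

`tension_fixture()` encodes the stated world of the tension experiments:
tabulated exponents, 30-point pH grids, and 2% relative Gaussian noise
applied multiplicatively (measurement error in tension scales with
signal; no error model is published, so this choice was made once). The
four component tensions are not published either. The fixture amplitudes
($A_X = -1.2, A_Y = -2.0$ mN/m for DPPC; $-1.4, -2.4$ for DPPE) were
chosen once so the curve rises from a lower acidic plateau, peaks, then
declines to a lower basic plateau — the qualitative published shape — with
$|A_X|+|A_Y| < B$ so every component tension stays non-negative. Given
the amplitudes, each baseline was solved numerically so the curve maximum
equals the tabulated $\gamma_{max}$ exactly; the solved baselines
(3.5042220553930174 and 4.005800783820769 mN/m) are frozen named
constants. The non-identifiable baseline split stored in `dppc_params()`
/ `dppe_params()` is likewise an arbitrary documented choice.

## Trajectory analysis

### Hydrogen-bond criterion

The reference bilayer analysis used its simulation package's internal,
energy-based H-bond definition, which is not published. This package uses
the field's standard geometric stand-in — donor–acceptor distance
≤ 3.5 Å and D–H⋯A angle ≥ 135°, both configurable via
`hbond_criteria()` — with minimum-image displacement on an orthorhombic
box (default 100 × 90 × 90 Å, the conventional bilayer box). Hydrogens
are assigned to the nearest heavy atom of their residue; donors are O/N
with at least one hydrogen, acceptors are O/N of *other* residues
(intra-residue bonds are excluded as topology, not chemistry). A water
oxygen without hydrogens is a topology error, not a silent non-donor.

### Bridges, contacts, lifetimes, maps

A water bridge is one water H-bonded (in either direction) to two
*different* lipids in the same frame — one event per (water, unordered
lipid pair); a doubly-bonded water on a single lipid is not a bridge.
Direct lipid–lipid H-bonds are contacts. Lifetimes are maximal runs of
consecutive frames containing an event key, `(last − first + 1) ×
spacing` (50 ps default), with a configurable gap tolerance that defaults
to 0 (strict lifetimes; a tolerance of $g$ bridges interruptions of up to
$g$ frames *and counts them into the lifetime*, which is the standard
residence-time bookkeeping). Bridge/contact maps count events per
unordered label pair normalized by the total event count. The map stores
each unordered pair once (at the alphabetically ordered position), so the
stored matrix sums to exactly 1; `map_matrix(symmetric = TRUE)` gives the
mirrored view in which off-diagonal pairs appear twice. The headgroup
oxygen numbering O1…O8 (plus N, P) is a documented package convention —
the published figures define their numbering only graphically — and is
remappable via `label_map` arguments.

### The toy trajectory generator and what a green test establishes

`gen_toy_trajectory()` builds a *constructed* world: rigid headgroup
scaffolds (a vertical column of sites per lipid, no acyl chains) on two
10 Å-pitch leaflet lattices, 3-site waters parked on sparse 6 Å grids in
the aqueous slabs, and planted events realized by exact geometry — bridge
waters midway between two adjacent anchors with their hydrogens aimed at
the two target sites (2.75 Å, collinear), contact donors swung toward
their acceptor (3.0 Å, collinear). Every planted bond beats the default
criteria with ≥ 0.3 Å / ≥ 10° to spare; every non-planted pair misses the
distance cutoff by ≥ 1 Å by layout (lattice pitch, slab separation, slot
spacing). Infeasible plants — two events on one lipid pair, a shared
water, a reused site, non-adjacent lipids — are rejected at generation.

This makes the generator/analyzer closure *exact*: the detector must
report precisely the planted events, frame by frame, and the lifetime
multisets must equal the planted intervals. A green closure test
establishes correct geometry, periodic-image handling, event logic and
bookkeeping. It deliberately does **not** establish anything about real
bilayers: there is no thermal disorder, no marginal geometry near the
cutoffs, no competing water network, and no realistic density. The
published bilayer-scale observations (the bridge-duration distributions
and the ~150%/~50% excess of bridges/contacts in the ethanolamine bilayer
over the choline one) would require nanosecond atomistic MD of
hundreds-of-lipid systems and are out of scope; the package's
`compare_counts()` and planted-ratio tests check the *definitions* of
those comparisons, not the biology.

## Numerical choices

* Charge-balance root: `uniroot` on pH (0, 14), tolerance 1e-15; the
  residual imbalance at the root is below 1e-12 M. Davies iteration stops
  when the ionic strength is stable to 1e-13 M (typically < 10 rounds).
* Grid-then-refine maximum location: 1e-3 pH grid, golden-section polish;
  the grid value is kept if refinement cannot improve it (exact ties).
* Sigmoid weights are computed in log10 space
  (`1/(1+10^(pH-pKX))`) to avoid overflow at extreme exponents.
* Table serialization uses 12 significant digits in scientific notation;
  write/read round trips are asserted lossless at that precision.
* Seeded RNG use is confined to `local_rng()`, which restores the
  caller's RNG state, so generators never perturb session reproducibility.

## Known limitations

* No ionic-strength model beyond Davies; no temperature dependence
  anywhere; no strong-acid titrants in the buffer module.
* The tension model has exactly two titratable groups; three-group lipids
  (e.g. phosphatidylserine) are not supported.
* PDB residue numbers are written modulo 10000 (fixed-width columns);
  toy systems stay far below that.
* The trajectory toolkit assumes orthorhombic boxes and 2-hydrogen
  (3-site) waters; lipid donors are limited to what the topology contains.
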