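---
title: "Functional-group corrections: model, fitting protocol and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-group corrections: model, fitting protocol and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgcorr)
```

## The correction model

Semiempirical (SQM) interaction energies are corrected by a pairwise sum over
*intermolecular* atom pairs,

$$E_\mathrm{corr} = \sum_{i \in A}\sum_{j \in B}
  f_\mathrm{cut}(r_{ij})\left[A_{ij}\,e^{-B_{ij} r_{ij}} +
  \frac{C_{ij}}{r_{ij}^{\,n_{ij}}}\right],$$

a Buckingham-type form whose parameters attach to the *pair type*: the
unordered pair of force-field-style atom-type labels carried by atoms $i$ and
$j$. The form is a practical correction, not a physically interpretable
potential: $A$ and $C$ may take either sign (the correction must be able to
both add and remove repulsion or attraction relative to the SQM baseline),
and $n$ is a small positive integer allowed to vary around 6 rather than
being pinned to the dispersion exponent. Energies are kJ/mol, distances Å.

The short-range damping is a logistic sigmoid,

$$f_\mathrm{cut}(r) = \frac{1}{1 + e^{-s\,(r - d)}},$$

chosen as the simplest function satisfying the properties the cutoff must
have: it is exactly $1/2$ at $r = d$, strictly increasing, vanishes as
$r \to 0$ for the steepness values in use, and tends to 1 at long range so
the correction is undamped where it matters. With the packaged values
($s = 10$ throughout, $d$ between 1.0 and 1.8 Å) the correction is
essentially switched off below ~0.8 Å — a region where the SQM repulsive
wall dominates anyway and where inverse powers of $r$ would otherwise
explode. The sigmoid exponent is clamped to $\pm 500$ before
exponentiation; beyond that the value is 0 or 1 to double precision, so the
clamp changes nothing numerically while preventing overflow.

Key model assumptions, stated explicitly:

* **Rigid monomers.** Scans freeze intramolecular geometry; the correction
  has no intramolecular terms and no meaning for covalent rearrangements.
* **Pairwise additivity.** No three-body terms; the correction for a trimer
  is the sum over its three dimer faces.
* **Externally supplied energies.** The package never computes reference or
  SQM energies. They enter as tabulated curves; the model only sees their
  difference.

## Atom typing

Types are assigned by ordered rules over the element and its bonded
environment, with connectivity inferred from the standard covalent-radius
criterion (bond when $r < 1.2\,(\rho_i + \rho_j)$, Cordero radii): a
deterministic heuristic with no dependence on a perception library. Rules for
hydrogen match on the *type label* of the attached heavy atom, so typing runs
in passes until a fixed point; an atom matching no rule is an error, never a
silent default.

The built-in rule set covers the three study monomers. Formic acid receives
five distinct labels — `C` (carboxyl carbon), `O` (carbonyl oxygen), `OH`
(hydroxyl oxygen), `HO` (hydroxyl hydrogen), `HCO` (carbon-bound hydrogen) —
so its homodimer exhibits $5 \cdot 6 / 2 = 15$ pair types. Ammonia gets
`N`/`HN` (3 pair types in the homodimer) and methane `CM`/`HM`; the methane
and ammonia labels are this package's own symbols, kept distinct from the
formic acid labels because the corresponding parameters are not shared across
functional groups. Missing pair parameters raise an error naming the pair:
contributing silent zeros would mask typing bugs.

## Scans and orientations

An orientation fixes the rigid pose of both monomers and designates one
*attack atom* in each; the scan coordinate is the attack-atom separation
$r$, realised by translating molecule B so its attack atom sits exactly at
$r$ along the approach axis. How monomers are rotated about that axis is part
of the orientation, not of the scan: `build_orientation()` takes explicit
azimuthal angles, so a pose is fully specified and reproducible rather than
left to an implicit convention. The default grid spacing is 0.1 Å, the usual
IPEC resolution; grids are validated to be strictly increasing and positive.

Before fitting, curves are capped at a maximum repulsive energy
(`apply_energy_filter()`); fitted data sets in this field typically extend to
caps between roughly 23 and 141 kJ/mol depending on orientation, and the
synthetic generator draws its per-orientation caps from exactly that range.

## The fitting protocol

All pair types of a system are fitted **simultaneously**: the genome
concatenates $(A, B, C, n)$ in canonical pair-key order — 60 genes for the
15 pair types of a five-type homodimer, 40 for four types, 24 for three. The
cutoff constants $(s, d)$ are fixed per pair type, never fitted: exploratory
fits that include them tend not to improve the result and inflate the search
space. When the user supplies no cutoff table, $d$ follows the atom-pair
class pattern of the packaged set (1.0 Å for H–H, 1.2 Å heavy–H, 1.7 Å
heavy–heavy, 1.8 Å C–C) with $s = 10$.

The objective is $\chi^2 = \sum_k w_k (y_k - E_\mathrm{corr}(x_k))^2$ with
unit weights by default. The optimizer is an elitist generational genetic
algorithm: tournament selection ($k = 3$), blend (BLX-$\alpha$, $\alpha =
0.5$) crossover for the reals with uniform parent choice for $n$, Gaussian
perturbation (10 % of the bound range) for real mutation and uniform random
reset for $n$, two elites carried over each generation. Defaults are a
population of 200 and 500 generations; elitism makes the best-so-far
$\chi^2$ non-increasing by construction, which the tests assert. Default
bounds — $A \in [-5\times10^5, 5\times10^5]$, $B \in [0.5, 8]$,
$C \in [-5\times10^3, 5\times10^3]$, $n \in [1, 12]$ — envelope the
magnitudes of the packaged parameter set with margin.

Because the landscape is smooth in the 3 real parameters per pair once the
integers are chosen, the GA is followed by a bounded Levenberg–Marquardt
polish (`minpack.lm::nls.lm`) of the reals at fixed $n$, accepted only if it
lowers $\chi^2$. This hybrid converges far faster than the GA alone at
desk scale. Multi-start is available (`n_starts`), each restart using a
derived seed; the default is a single start, since the polish removes most of
the run-to-run spread and a user wanting the classic best-of-several protocol
can raise it explicitly.

Every fit requires a seed, echoes it in the result, and is bit-exactly
reproducible from it; the fitter restores the caller's RNG state.

**Identifiability.** The model is deliberately overcomplete: many genomes
produce nearly identical correction *curves*. Recovery is therefore defined —
and tested — in curve space (RMSE of the fitted model against the truth
difference curves), never as agreement of individual parameters.

**Nested typings.** Merging atom types (e.g. treating both oxygens of a
carboxyl group as one type) produces a model nested inside the finer one, so
its best achievable $\chi^2$ can only be equal or worse. The package realises
the nesting operationally: `merge_types()` relabels a dataset,
`expand_params()` lifts a coarse solution onto the finer typing, and the
expanded genome is injected into the finer fit's initial population
(`init_genomes`). With elitism this warm start guarantees the nested
$\chi^2$ ordering deterministically instead of leaving it to optimizer luck —
the protocol the reproduction script runs with 5 → 4 → 3 formic-acid-like
types.

## The synthetic-data generator

`synthetic_spec()` and its generators stand in for the electronic-structure
inputs a real campaign would use. Per orientation, the mock "SQM" baseline is
a Morse-like well $D_e[(1 - e^{-a(r - r_e)})^2 - 1]$ with depth, range and
minimum position drawn from realistic IPEC ranges (2–15 kJ/mol, 1.5–2.5 Å⁻¹,
3.2–4.2 Å); the mock reference adds a ground-truth pairwise correction and
optional Gaussian noise, so the reference-minus-SQM differences equal
truth-correction-plus-noise by construction and, at zero noise, $\chi^2 = 0$
is attainable exactly. Ground-truth amplitudes are drawn to span the
magnitude range of the packaged parameters ($|A|$ up to $3\times10^5$, $|C|$
up to $3\times10^3$), so the fitter is exercised at realistic scales.
`make_orientations()` enforces the coverage rule that the number of
orientations is at least the number of pair types, and makes every pair type
the attack pair of at least one orientation.

What the generator does *not* emulate: electrostatics, induction, charge
transfer, BSSE artifacts, anisotropy beyond what rigid poses induce, or any
correlation structure in the noise. Passing the recovery tests therefore
demonstrates that the optimizer and model pipeline are correct and
well-conditioned on data the model can represent — not that the functional
form suffices for any particular real complex (the ammonia lone pair is a
known hard case for this form, for instance).

## Numerical choices

* Distances, cutoff values and pair energies are evaluated vectorised over
  all intermolecular pairs; equality with a naive double loop to 1 × 10⁻⁹
  kJ/mol is an explicit test and acceptance quantity.
* The analytic gradient uses $dE/dr$ per pair projected on the unit
  separation vector; atomic gradients sum to zero (translation invariance)
  and match central finite differences ($h = 10^{-5}$ Å) to 1 × 10⁻⁶
  kJ mol⁻¹ Å⁻¹.
* CSV writers format numerics as `%.17g` and readers parse via `strtod`, so
  curve and parameter files round-trip bit-exactly.
* Pair keys sort lexicographically and the genome follows that order; all
  tie-breaks are therefore deterministic.
* The inverse-power term makes $r \to 0$ singular; `pair_energy()` rejects
  non-positive distances, and the low-$n$ tails mean the correction decays
  slowly — a pair with $n = 2$ still contributes ~3 × 10⁻³ kJ/mol at 100 Å.
  Decay assertions in the tests use separations where the bound genuinely
  holds.

## Error metrics

`mae()` is the mean absolute deviation; `mbe()` is fixed as
**mean(reference − model)**, so a model that under-binds an attractive set
has a *negative* bias. This convention is stated prominently because the
opposite sign is equally common in the literature. `correlation_report()`
regresses model on reference (model on the ordinate) and reports slope,
intercept and $r^2$ alongside MAE/MBE and the point count — error statistics
are only comparable between matched conformer sets.

## Problem sizes used by the tests

The shipped tests and the acceptance script run the recovery study on a
two-pair-type heterodimer of diatomics (7 orientations, ~220 points,
population 100, 120 generations) and the nested-typing study on a
formic-acid-like homodimer (15 orientations, 0.25 Å grid, ~175 retained
points, population 80, 60 generations, polish capped at 40 iterations).
These sizes were chosen as the smallest at which the studies are
well-conditioned; they are the package's own defaults for its worked
examples, and all scale up linearly if a user wants production-size fits.

## Known limitations

* No three-body (Axilrod–Teller–Muto-type) terms and no lone-pair
  pseudoatom sites; systems whose errors are dominated by those physics
  (ammonia-like donors, water) will fit poorly no matter the optimizer.
* Typing is rule-based over configured functional groups, not general
  substructure perception; unknown environments error out by design.
* No periodic boundary conditions and no BSSE handling — inputs are assumed
  counterpoise-corrected upstream.
* Parameters are transferable only within the functional groups they were
  fitted on; applying, say, carboxyl-derived carbonyl parameters to ketones
  is known to fail and is the motivation for *functional-group-specific*
  corrections in the first place.
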