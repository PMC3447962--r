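---
title: "Structure-based sampling and SAXS ensemble analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-based sampling and SAXS ensemble analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A multi-domain enzyme whose domains are joined by flexible linkers does
not sit in the single conformation a crystal structure shows. In
solution it populates an ensemble of compact and extended arrangements,
and a small-angle X-ray scattering (SAXS) curve measures the
population-weighted rotational average over that ensemble. A single
curve therefore cannot be inverted into one structure; but it can
discriminate among *candidate* ensembles. This package implements the
pool-based strategy: generate a large, physically plausible pool of
conformations from a structure-based simulation, score every conformer
against the measured curve, and search small weighted mixtures of
representative conformers for the combination that reproduces the data.

# The structure-based model

## Potential

The forcefield is an all-atom (heavy-atom) structure-based (Gō-type)
model: its global minimum is the native input structure. The energy is

* bonds: $\varepsilon_r (r - r_0)^2$ with
  $\varepsilon_r = 100\,/\text{Å}^2$;
* angles: $\varepsilon_\theta (\theta - \theta_0)^2$ with
  $\varepsilon_\theta = 20\,/\text{rad}^2$;
* impropers/planarity: $\varepsilon_\xi (\xi - \xi_0)^2$ with
  $\varepsilon_\xi = 10\,/\text{rad}^2$;
* proper dihedrals: $w\,F(\varphi)$ with
  $F(\varphi) = [1-\cos(\varphi-\varphi_0)] +
  \tfrac12[1-\cos 3(\varphi-\varphi_0)]$;
* native contacts: Lennard-Jones 12-6,
  $\varepsilon_C [ (r_{nat}/r)^{12} - 2 (r_{nat}/r)^{6} ]$, minimum at
  the native distance;
* excluded volume: $\varepsilon_{nc} (\sigma_{nc}/r)^{12}$ over all
  non-excluded pairs, $\varepsilon_{nc} = 0.01$,
  $\sigma_{nc} = 2.5$ Å.

All reference values ($r_0, \theta_0, \xi_0, \varphi_0, r_{nat}$) are
read from the input structure. Energies are in reduced units; the
dihedral function $F$ is the standard all-atom SBM form (the single
$2\pi$- plus $2\pi/3$-periodic cosine pair).

## Shadow contact map

A native contact is an atom pair (a) closer than 6 Å, (b) at least 4
residues apart in sequence (pairs on different chains always qualify),
and (c) with an unoccluded line of sight: no third atom within the
contact cutoff of both partners passes within the screening radius
(1 Å) of the open segment joining them. The screening test is the
published operationalization of the Shadow algorithm; the sequence rule
is read as $|i - j| \ge 4$. The map is validated against a literal
brute-force oracle in the test suite.

## Multi-domain treatment

Only steric interactions act between domains: every contact whose two
atoms carry different domain labels is deleted (linker atoms count as
their own label, so linker–domain contacts are removed too, maximizing
linker freedom), and non-rigid dihedrals whose four atoms do not share a
single domain label carry zero weight. Rigid (sp²-like) dihedrals keep a
fixed stiffness everywhere, so chemistry such as peptide-bond planarity
is never freed.

## Energy normalization

Stabilizing energy is distributed as
$\sum \varepsilon_C + \sum w = N_{atoms}\,\varepsilon_{unit}$ with a
2:1 contact:dihedral split, equal $\varepsilon_C$ per contact and equal
$w$ per weighted dihedral — the standard all-atom SBM convention. If one
class is empty its share moves to the other.

## Bond perception and rigidity detection

Covalent connectivity is perceived geometrically: a bond is any pair
closer than the sum of covalent radii plus 0.4 Å (this also yields the
disulfide rule, S–S out to ~2.5 Å). One proper dihedral is assigned per
rotatable central bond (lowest-index flanking atoms); a centre with
exactly three neighbours whose native improper is within 10° of planar
is treated as sp²-like, receiving a harmonic improper and rendering its
dihedrals rigid. A template-based perception keyed to residue names
would be equivalent for standard amino acids; the geometric rule was
chosen because the package must handle both real PDB chemistry and the
synthetic toy structures with one code path.

# Sampling

Langevin dynamics with the BAOAB splitting at timestep 0.0005 reduced
time units, unit atom masses, and a snapshot every 0.5 time units; the
production protocol integrates 20,000 time units for 40,000 candidates.
Scaled-down runs shorten the total time, never the snapshot interval.
With friction 0 the integrator reduces exactly to velocity Verlet (the
suite checks energy conservation there), and at temperature 0 it is a
damped descent to the native minimum. Temperature and friction are not
fixed by the protocol this model family inherits; the defaults (1.0
reduced each) target near-native-basin sampling and are exposed in the
sampler parameters. An optional burn-in (`equilibration`) discards an
initial segment, which matters when a run starts from constructed
(hinge-rotated) coordinates that can carry steric clashes.

The excluded-volume pair sum uses a Verlet neighbour list (cutoff
3σ_nc, 2 Å skin, rebuilt every 200 steps — a conservative margin at
this timestep and temperature range) and a 1-2/1-3/1-4 plus
native-contact exclusion list. Energy divergence (|V| beyond a
configurable bound) aborts with a diagnostic rather than producing
garbage frames. Analytic forces are validated against central
differences; dihedral gradients use the standard four-point torsion
force relations with translational-invariance closure.

# Scattering theory

Profiles are computed with the exact Debye double sum over atom pairs
with 4-Gaussian Cromer–Mann vacuum form factors (f(0) equals the
electron count to better than 1e-3), optionally minus a Gaussian
dummy-atom solvent term (displaced volumes per element, bulk water
density 0.334 e/Å³). A spherical-harmonics expansion with an explicit
hydration shell (the CRYSOL approach) is deliberately *not*
reimplemented: at q ≤ 0.18 Å⁻¹ the exact Debye sum is the reference
computation, it is directly checkable against a naive double-loop
oracle, and the scale-fitted χ² used downstream absorbs residual
amplitude-level differences between scattering models. The default grid
mirrors the standard acquisition range: 100 points, q ∈ [0.01, 0.18]
Å⁻¹; q = 0 is handled by the analytic sinc limit when requested.

Guinier analysis fits ln I against q² by error-weighted least squares
over the self-consistent window q·Rg ≤ 1.3, iterating the window to
stability; a non-negative low-q slope raises an error rather than
returning a meaningless radius. The Kratky transform I·q² is provided
for fold-compactness diagnostics.

# Ensemble analysis

Scoring uses the reduced chi-square with a fitted multiplicative scale,
$c = \sum(I_{exp} I_{theo}/\sigma^2) / \sum(I_{theo}^2/\sigma^2)$;
simulated intensities are on an arbitrary scale, so a scale-free
comparison would be meaningless. No additive background is fitted.

The low-χ² filter keeps the `floor(fraction · N)` best conformers
(default 5%; 2.5% and 7.5% serve as a robustness check), breaking ties
toward earlier frames so the operation is deterministic. P(Rg) is a
fixed-width normalized histogram (default bin 0.25 Å, anchored at
multiples of the bin width so different subsets share a grid); peaks are
local maxima whose topographic prominence exceeds 5% of the tallest
bin, with the outside of the grid treated as empty bins so edge peaks
get their full prominence. Representative selection takes, per peak, the
lowest-χ² conformers inside the contiguous half-height window that are
mutually distinct (superposed RMSD above a threshold, default 2 Å),
greedily in χ² order.

Weight vectors are enumerated as integer compositions of 1/step
(default step 0.1, the 66-vector grid for three members), so weights
sum to one exactly in integer arithmetic; zeros are allowed, which lets
the search drop a population entirely. The ensemble search evaluates
every weight vector for every cross-product choice of one
representative per peak (4×4×4 = 64 candidate ensembles with defaults)
and returns the global χ² minimum, ties broken toward the
lexicographically smallest weight vector. The cross-condition table
refits each best ensemble's combined curve against every condition's
data; when each condition is genuinely different, its own ensemble is
the row minimum on the diagonal.

# Synthetic data: what it emulates, and what it does not

The generator builds multi-domain toys — compact self-avoiding random
clusters (1.5 Å bonds, ≥ 2.2 Å non-bonded separations) strung along an
axis by extended linkers — plus conformer families (rigid hinge
rotations about linker pivots, optionally with per-hinge angle scaling
to produce L-shapes; or delegation to the sampler) and mock experimental
curves: $I(q) = \sum w_i I_i(q) + \epsilon(q)$,
$\epsilon \sim N(0, \sigma(q))$,
$\sigma(q) = 0.01\, I(q)\, (1 + 3 q/q_{max})$. The multiplicative noise
with linear q-inflation reproduces the error growth of real detectors
in this q range without modelling beamline specifics; buffer mismatch,
radiation damage and interparticle structure factors are out of scope.
Toy domains are random globules, not real folds: tests passing on them
demonstrate that the geometric, scoring and search machinery is
correct, not that the model reproduces any particular protein.

# Validation design and problem sizes

The validation suite runs at desk scale. The shared candidate pool is a
two-domain toy (40 atoms per domain, 8-atom linker) sampled in three
Langevin runs of 400 time units (2,400 snapshots) started from
hinge-opened conformations — the multi-start design covers compact
through extended shapes within a short wall-clock budget, mirroring the
one-pool/many-conditions production layout. Weight-recovery experiments
use three mutually distinct conformers chosen by a greedy max–min
profile-shape criterion from uniform-fold and L-shape hinge families of
a three-domain toy; this is the synthetic analog of requiring
representatives to be structurally distinct. Desk-scale analysis
parameters are scaled with the toys: 0.5 Å bins for cross-fraction peak
comparisons, 0.25 Å for P(Rg) within one condition, and a 1 Å
representative-distinctness threshold (the toys' Rg is roughly a third
of a full-length kinase's, so the production 2 Å threshold over-prunes
them). Production defaults are unchanged.

# Identifiability and known limitations

Scattering mixtures are low-information. Three lessons from the
validation work are worth stating plainly:

* **Grid-weight recovery needs linearly independent members.** Members
  of a single hinge family lie on an effectively one-parameter curve
  manifold; the middle member is nearly a linear combination of the
  endpoints, and at 1% noise the weight grid cannot distinguish the
  true mixture from neighbouring ones. Recovery experiments therefore
  use members from different shape classes.
* **The low-χ² filter concentrates, it does not resolve.** Conformers
  are filtered by *individual* fit to the mixture curve, so the
  filtered set clusters around the single best-fitting shape region; it
  will not, in general, contain all the well-separated generators of a
  synthetic mixture. Consequently the pipeline's closure checks assert
  what the method can deliver — the fitted ensemble reproduces the
  data at the noise floor, carries the ground truth's Guinier radius,
  and each condition's ensemble fits its own data best — rather than
  exact identity of members through the filter. P(Rg) peaks of a
  filtered set are fine-structure within the best-fit region, and at
  desk-scale counts their secondary peaks are sampling noise; only the
  dominant peak location is asserted across filter fractions.
* **Ensemble weights are curve-equivalent, not unique.** Different
  member/weight combinations can produce indistinguishable curves; the
  reported ensemble is the best grid point, not a posterior. Continuous
  weight optimization and uncertainty on weights are deliberately out
  of scope.

Other limitations: no hydration-shell contrast model (see the
scattering section); no additive background term; hinge mode assumes
rigid domains; the toy generator does not emulate real folds or
beamline artifacts; and experimental reference values for the
motivating kinase system require the original (undeposited) beamline
curves, so all quantitative validation is against synthetic ground
truth and independent numerical oracles.

# Reproducing the numbers

`scripts/acceptance.R --seed <s> --out <path>` recomputes every
validation quantity from scratch — oracle agreements, the exact native
minimum, Shadow-map equivalence, the χ² and weight-grid hand examples,
20-seed weight recovery, filter robustness, and the three-condition
cross-fit — deriving all randomness from the one seed, and writes them
as JSON. The README shows a worked example whose printed output comes
from running the code as shown.
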