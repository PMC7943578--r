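---
title: "Mapping the open/closed equilibrium of a switchable helical barrel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the open/closed equilibrium of a switchable helical barrel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelswitch)
```

## The system and the question

Coiled-coil assemblies of six or more amphipathic helices can adopt two
qualitatively different folds under one set of conditions. In the *open*
form the helices sit on a circle with cyclic (C6) symmetry, leaving a
continuous hydrophobic channel along the bundle axis — an α-helical barrel.
In the *closed* form the two three-helix sheets of the hexamer shear past
each other perpendicular to the barrel axis and pack into a C2-symmetric
α-helical sandwich with a consolidated core and no channel. A hexamer with
a `gade`-type interface (Leu at `a`, Ile at `d`) and glycine substituted at
the `e` sites is frustrated between these folds: β-branched Ile at `d`
sterically favours the open barrel, the hydrophobic effect favours
collapse, and glycine's missing side chain lets the helices approach
closely enough for the collapsed alternative to compete. An ensemble of
such a peptide therefore populates several metastable states spanning the
open↔closed coordinate.

`barrelswitch` quantifies that equilibrium for conformational ensembles:
it featurizes frames by their distance to the two endpoint structures,
estimates the free-energy landscape over those coordinates, extracts
metastable states and their populations, and characterises each state's
geometry (channel radius), packing (knobs-into-holes) and solvent exposure
of interface reporters. A companion module fits ligand-titration curves
with the quadratic tight-binding model.

## Conformational coordinates: symmetry-aware RMSD

Each frame is reduced to the pair

\[ (d_\mathrm{closed}, d_\mathrm{open}) =
   (\mathrm{RMSD}_\mathrm{bb}(x, X_\mathrm{closed}),\;
    \mathrm{RMSD}_\mathrm{bb}(x, X_\mathrm{open})) \]

where RMSD is over all backbone atoms (N, CA, C, O — the conventional
backbone set; Cβ excluded) after a single joint Kabsch superposition of all
six chains. The six chains of a homohexamer are physically
interchangeable, so the chain *names* of a frame need not match the
reference: a frame identical to the reference but with its dimer interface
between a different chain pair would show a large RMSD purely through
labelling. Both RMSDs are therefore minimised over the six cyclic
rotations of the reference chain names
(`[(A B C)(D E F)], [(B C D)(E F A)], …`). Only cyclic rotations are
considered — reflected or anti-parallel matchings would superpose a
left-handed interface onto a right-handed one and are excluded by
construction. Ties between topologies (exact for a perfectly symmetric
reference) resolve to the lowest index.

Superposition uses the closed-form Kabsch algorithm with the determinant
correction, so the rotation is always proper (det = +1) and the reported
RMSD is the global minimum over rigid motions. Whether to superpose on all
six chains jointly or on a subset is a genuine choice; the joint
superposition is used because the coordinate is meant to measure *global*
closure, not per-sheet similarity.

## Landscape estimation and metastable states

The density of frames in the 2-D coordinate plane is estimated with a
full-covariance Gaussian mixture (EM, `mclust`). Two choices deserve
comment:

* **Component count.** The number of Gaussians is selected by BIC over a
  user-given range (default 1–10). BIC is deterministic and penalises
  overfitting; the mixture is a *density* model, so the component count
  need not equal the number of metastable states.
* **Initialisation.** EM is initialised by model-based hierarchical
  clustering on a seeded random subsample (one fifth of the frames, capped
  at 2000 points), after which all frames enter the fit. This mirrors the
  practice of initial clustering on a data subset, keeps the cost of the
  hierarchical step bounded, and makes the whole fit reproducible from one
  integer seed. A multi-restart EM was considered and rejected: the
  deterministic hierarchical initialisation removes the restart lottery
  altogether, which matters more for reproducibility than the marginal
  likelihood gain of many random restarts.

The free-energy surface is \(F(x) = -kT \log \hat p(x)\), evaluated on a
151×151 grid spanning the feature ranges with 5% padding, shifted so the
minimum is exactly zero, and masked (set to ∞) above a 6 kcal/mol cap
where the density estimate is no longer meaningful. The default
\(kT = 0.5826\) kcal/mol corresponds to 293.15 K. Contour plots use
0.25 kcal/mol spacing.

Metastable **core states** are basins of the mixture density, in the
spirit of inflection-point (InfleCS-style) clustering: each component mean
is carried uphill by gradient ascent (backtracking line search on the
analytic mixture gradient); means converging to the same maximum (within
2% of the feature-range diagonal) form one basin. A frame is assigned
crisply to the basin of its maximum-responsibility component only if that
responsibility is ≥ 0.5 **and** its density is above the 20th percentile
within the basin; all other frames are transition points and stay
unassigned, so they cannot dilute state statistics. Populations are
core-member fractions renormalised over assigned frames. The exact
inflection-point threshold of the original method is not reproducible from
its description, so the responsibility-plus-density-quantile surrogate is
used and documented as such; renormalising over assigned frames only is
likewise a documented choice.

Sampling convergence is checked by refitting on a random 1/50 subsample
and comparing (i) the free energy over the basin region (nodes within
3 kcal/mol of the minimum, Pearson correlation) and (ii) matched state
populations. For well-sampled data the correlation should exceed ~0.95
and populations should agree to a few percentage points.

## Bundle geometry and channel profiling

Helix axes are estimated per chain from the CA trace (first and last two
residues trimmed): the direction is the screw axis of the one-residue step
(the rotation axis of the optimal superposition of the trace onto itself
shifted by one residue), which is exact for an ideal helix — unlike the
principal axis of a non-integer number of turns, which is biased by
~0.01 rad; the axis point is the centre of the circle the CAs describe
around that direction. The bundle axis is the sign-aligned mean of the
helix directions: the first principal axis of the six near-coplanar
centroids would pick an in-plane direction and is wrong for a barrel.
Neighbour identity (for CA spacings and triad angles) is the angular order
of the axis centroids about the bundle axis, which for the sheared
sandwich may differ from chain-name order.

Channel radii follow the largest-inscribed-sphere (HOLE-style) picture:
at each 1 Å slice along the bundle axis, the radius of the largest sphere
centred in that slice plane touching no van der Waals sphere
(C 1.70, N 1.55, O 1.52, S 1.80 Å; the builder's side-chain pseudo-centroid
`SC` carries 2.20 Å because it stands for several heavy atoms). The centre
is optimised by Nelder–Mead, seeded at the bundle axis in the middle slice
and then *tracked*: each successive slice starts from the previous centre
and may drift at most 1 Å, and centres are confined to the convex hull of
the helix-axis positions. The tracking matters: a collapsed sandwich
retains scattered interstitial voids above the 0.5 Å slice threshold, and
an unconstrained per-slice search happily hops into grooves between sheet
edges that are not a pore. A bundle *has a channel* only when one
contiguous open span covers at least half the slices — a pore must be
continuous to be traversable, which is also the operational sense in which
a collapsed crystal structure supports no channel computation. Per-state
channel radii average per-conformation mean radii over representative
conformations sampled uniformly (with replacement, seeded) from each core
state; channel-less conformations are counted separately.

## Packing and burial

Knobs-into-holes detection uses the SOCKET-style count rule: a residue is
a *knob* when its side-chain centroid (mean of non-backbone heavy atoms;
glycine has none and can line a hole via its CA but never be a knob) lies
within 7.0 Å of the centroids of at least four residues on a single other
chain; the four nearest form the *hole*. No angular complementarity test
is applied — this is a deliberate simplification relative to full SOCKET,
adequate for counting and classifying interactions. Classification:
*cyclic* interactions are `a`/`d` knobs docking into the cyclically
adjacent chain with one consistent rotational direction around the bundle
(the barrel's classical packing); *inter-sheet* interactions join chains
of different three-helix sheets that are not cyclically adjacent (the
collapsed state's hallmark); the remainder (e.g. `b`, `c`, `e`, `g` knobs
between adjacent chains) are *non-cyclic*.

SASA uses Shrake–Rupley sampling (960 golden-spiral points, probe 1.4 Å).
The burial analysis classifies the reporter residue's Cβ per chain and
conformation as buried (SASA < 10 Å²; the boundary value counts as buried)
or exposed, and weights per-state fractions by state populations to give
ensemble-averaged occupancies of the two environments — the quantity that
connects the simulated ensemble to NMR peak ratios of a labelled reporter.

## Ligand binding

Titrations with a constant component at total concentration \(c\)
(e.g. a fluorophore at 0.1 µM) and a variable component at \(x\) follow
the quadratic ("tight-binding" / ligand-depletion) model

\[ y = B_\mathrm{max}\,
   \frac{(c + x + K_D) - \sqrt{(c + x + K_D)^2 - 4cx}}{2c}. \]

Only the minus root is physical: it gives \(y(0) = 0\), increases
monotonically, saturates at \(B_\mathrm{max}\), and reduces to the
hyperbola \(B_\mathrm{max}\,x/(x + K_D)\) for \(c \ll K_D\). The plus
root is unbounded and non-zero at zero titrant, so a fit to it cannot
describe a titration; the package implements the minus root and states
this prominently in `fraction_bound()`'s documentation. \(c\) is fixed at
its known experimental value during fitting (it is not identifiable
together with \(K_D\) from a single curve). Fitting is multi-start
Levenberg–Marquardt over a log-spaced \(K_D\) grid (10⁻³–10³ µM, 7
starts); confidence intervals come from a seeded residual-resampling
bootstrap (1000 replicates by default). A \(K_D\) interval spanning more
than a factor of 10 flags an unidentifiable fit, e.g. a titration that
never approaches saturation.

## The synthetic generator

All tests and the acceptance analysis run on generated data, built to
emulate the *structure* of the study system:

* **Open barrel.** Six identical ideal α-helices (internal-coordinate
  build: φ = −57.8°, ψ = −47.0°, standard bond geometry; backbone plus Cβ
  and a per-residue-type side-chain pseudo-centroid `SC`), placed with
  exact C6 symmetry at superhelix radius 8.5 Å, hydrophobic `a`/`d` faces
  pointing at the lumen. The default 28-residue sequence is a 4×`KEIGQAL`
  heptad with register offset 1, so Leu sits at `a`, Ile at `d`, Gly at
  `e`, and the reporter Ala-13 at `g` — the interface layout of the
  switchable hexamer. Helices are straight and parallel by default
  (infinite supercoil pitch keeps the symmetry properties exact; a finite
  pitch is supported).
* **Closed sandwich.** Built from the barrel by per-chain rigid
  transforms: the two three-helix sheets (F, A, B) and (C, D, E) are
  flattened onto planes 7.2 Å apart, with 9.2 Å in-sheet spacing and a
  relative slide of a quarter spacing so the sheets interleave into a
  compact quasi-lattice. Opposite chains get equal-and-opposite
  translations, making the sandwich *exactly* C2-symmetric. The
  construction was chosen over shearing rigid arc-shaped half-barrels:
  rigid arcs geometrically cannot nest — their tips clash while the lumen
  stays open — whereas the crystallographic collapse also deforms the
  sheets internally (its per-helix translations differ within a sheet).
  The flattened construction trades exact per-helix crystallographic
  translation magnitudes for the correct phenomenology: exact C2, no
  steric clashes, and a genuinely collapsed lumen.
* **Ensembles.** Frames are drawn from a mixture of states on the
  interpolation coordinate λ (0 = open, 1 = closed): state by weight,
  λ ~ N(centre, spread) clipped to [0, 1], coordinates interpolated
  linearly between the superposed endpoints, plus isotropic Gaussian
  noise. The default `paperlike` preset has six states with populations
  (5, 5, 5, 10, 60, 15)% spanning the closed-to-open coordinate, the
  dominant state near mid-coordinate and the most open state modestly
  populated — illustrative of the described state structure, not a fit to
  it. Defaults: λ spreads 0.015 and coordinate noise 0.25 Å, giving
  clearly separated, well-defined states (separation ≈ 5 intra-state
  standard deviations). Linear Cartesian interpolation is an acknowledged
  surrogate for the unknown geometry of intermediate (slipped) states; it
  is adequate here because the features themselves are Cartesian RMSDs.

What the generator does *not* emulate: solvent and co-solvent physics,
side-chain rotamers (a single pseudo-centroid per residue), kinetics
(frames are i.i.d., not a trajectory), and the specific basin shapes of
the real landscape. Passing tests therefore demonstrate that the analysis
chain recovers known mixture structure, symmetry and geometry from data of
this kind — not that it reproduces any particular simulated trajectory.

## Numerical choices and degenerate inputs

* Covariances are regularised by 10⁻⁶ on the diagonal; mixture densities
  are floored at the smallest normal double before logs.
* Landscape correlation reports exclude masked nodes; the basin region for
  convergence checks is capped at 3 kcal/mol above the minimum.
* Exact topology ties (symmetric references) resolve to the lowest index;
  gradient ascent uses backtracking with a 1.5× growth factor and stops on
  relative gradient-step size 10⁻⁸.
* Structures with incomplete backbones fail featurization with the
  offending residues listed; zero-occupancy atoms are retained on read and
  excluded from selections via `occ > 0` when desired.
* Channel profiles of structures whose common helix extent is shorter than
  one slice return a single-slice profile; entirely empty structures are
  rejected.
* Problem sizes used in the shipped tests and acceptance analysis: 5000
  frames for the six-state run, 20000 points for the 3-Gaussian benchmark,
  25 representative conformations per state for channel/burial summaries,
  20–100 seeds for binding simulation studies. These sizes give the
  statistical resolution the assertions need (e.g. binomial standard
  errors well below the population tolerances).

## Known limitations

* The reduced-atom representation cannot reproduce absolute channel radii
  or SASA of all-atom structures; comparisons are meaningful within the
  representation (open vs closed, state vs state).
* KIH counts depend on the 7.0 Å cutoff; sensitivity within 6.5–7.5 Å
  should be checked when comparing structures of different compactness.
* The crisp-core surrogate differs in detail from the original
  inflection-point criterion; populations near 50% responsibility
  boundaries can shift by a point or two under reasonable alternative
  thresholds.
* The worked example against the deposited two-hexamer crystal structure
  (PDB 6ZT1) requires a network download at run time; all other analyses
  are fully self-contained.
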