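---
title: "Methods: ion-site assignment, pore profiling and bi-ionic selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ion-site assignment, pore profiling and bi-ionic selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionpore)
```

This vignette explains the models and procedures implemented in ionpore, the
parameters that matter, and the choices made where the design was genuinely
open. The motivating system is the lysosomal K⁺ channel TMEM175 — a
homodimer whose two internally duplicated 6-helix repeats give the pore an
approximately four-fold environment, whose gate is a ring of isoleucine side
chains rather than a canonical TVGYG filter, and whose ion-binding sites are
coordinated mostly by ordered waters. None of the algorithms are specific to
that channel.

## Dual-cation ion-site assignment

Cryo-EM density alone rarely distinguishes a bound K⁺ from an ordered water:
both are roughly spherical peaks of similar size, and in a pore without
dedicated coordinating chemistry the local environment is uninformative. The
assignment procedure exploits differential cation scattering instead. Two
maps are determined under conditions differing only in the permeant cation —
K⁺ versus Cs⁺, where Cs⁺ scatters electrons about three times more strongly.
A genuine ion site produces a peak in both maps, much stronger in Cs⁺; a
water produces equal peaks in both, which at a suitably stringent threshold
survive only in the K⁺ map.

The implementation:

1. **σ-scaling** (`sigma_scale()`). Map values are expressed in units of the
   full-grid RMS deviation about the full-grid mean — the convention in
   which deposition thresholds are quoted. Statistics are deliberately
   computed over the whole grid, not a masked region, so "12 σ" here means
   what it means in a map viewer. Scaling is idempotent and invariant to
   affine rescaling of the raw map; a constant map is rejected.
2. **Peak extraction** (`find_nonprotein_peaks()`). Voxels at or above the
   threshold are kept; voxels within an exclusion radius (default 1.8 Å) of
   any protein or other non-solvent model atom are removed, which deletes
   side-chain and backbone density while retaining solvent peaks; an
   optional region mask (by default a cylinder of radius 8 Å around the pore
   axis, since the analysis concerns the permeation pathway) restricts the
   search. The remainder is segmented into 26-connected components, each
   reduced to an intensity-weighted centroid, a maximum σ, a suprathreshold
   volume and its member voxels.
3. **Matching** (`match_peaks()`). "Overlapping" peaks are defined primarily
   by shared suprathreshold voxels (both maps are on the same grid after
   any model superposition), pairing largest overlap first, one-to-one. A
   centroid-based mutual-nearest-neighbor mode (default cutoff 1.5 Å, ties
   broken by smaller distance then higher partner σ) is available for maps
   on different grids. No overlap metric is canonical in the field; voxel
   overlap is the most literal reading of "overlapping density" and the
   centroid mode is the documented fallback.
4. **Classification** (`classify_sites()`). Matched peaks are ions, labelled
   K1, K2, ... in order of position along the pore axis; unmatched primary
   peaks are waters. Each ion carries an amplitude ratio: the partner peak's
   raw amplitude (max σ × that map's raw RMS) over the primary's. For a true
   ion site under the K⁺/Cs⁺ pairing this ratio is ≈3.

`site_geometry_report()` then lists model atoms within a shell of each site,
flagged as direct protein contacts or solvent-mediated ones, which is how
coordination distances (e.g. water layers 3.1–3.4 Å from a site) are read
out.

Elongated densities that may represent two partially occupied sub-sites
(the K3-like case) are reported as whatever the threshold yields — one
component at a permissive threshold may split at a stricter one. The
component count at each threshold is the honest answer; the package does not
adjudicate occupancy.

## Probe-radius pore profiling

The profile answers "what is the largest sphere that fits at each height of
the pore?". At each position z along the axis, the probe center is optimized
within the perpendicular plane to maximize clearance — the minimum over
protein atoms of (distance to atom center − van der Waals radius). Waters
and ions are never obstacles, so the profile describes the protein-lined
pathway. Key choices:

- **vdW radii**: a single Bondi-style table (C 1.70, N 1.55, O 1.52, S 1.80,
  H 1.20 Å; unlisted elements fall back to carbon). Published profiles from
  CHAP-class tools do not restate their table, so agreement is expected to
  ~0.2 Å, not bit-exact.
- **In-plane optimization**: multi-start Nelder–Mead (default 8 starts, one
  at the axis, the rest seeded uniformly in a disk), deterministic for a
  fixed seed. Clearance grows without bound outside the protein, so the
  objective is capped at the radius cap and the center is hard-bounded to
  `max_offset` (default 4 Å) from the axis, with a tiny (10⁻³ Å⁻¹) pull
  toward the axis to resolve plateau ties. For centered symmetric geometries
  this recovers the analytic clearance (ring radius − vdW) to well within
  the 0.05 Å test tolerance.
- **Axis**: by default the z axis through the protein centroid, which suits
  generated channels; for a real homodimer `estimate_pore_axis()` recovers
  the two-fold axis as the rotation axis of the chain-A-onto-chain-B Kabsch
  superposition. An explicit axis always overrides.
- **Step** 0.5 Å; **radius cap** 10 Å flags bulk solvent (`capped = TRUE`)
  so funnel mouths have a finite sentinel.
- `min_constriction()` returns the global minimum in a window, ties broken
  toward the smaller z (the cytoplasmic end, by the package's orientation
  convention), along with the residues realizing the contact (clearance
  within 0.2 Å of the optimum).
- `hydrophobicity_annotation()` scores each sample with the mean
  Kyte–Doolittle value of residues having an atom within `lining_cutoff`
  (default 6 Å) of the probe center; unknown residues contribute a neutral
  0 with a warning. Any named residue→value table can be supplied.

This is a static, single-model profiler: no solvent-accessible surface, no
grid-based cavity search, no trajectory averaging.

## Superposition and RMSD

`kabsch_superpose()` is the standard SVD solution with the determinant sign
correction, rejecting under-determined inputs (n < 3 or collinear).
`rmsd_between_models()` pairs atoms by (chain, residue number, atom name) or
through an explicit residue-range map (for comparing internally duplicated
domains, where TM1–TM4 of repeat I pair with their repeat II equivalents),
with a Cα-only fallback when paired residues differ in side-chain
composition. The default scope is protein atoms present in both models:
published "all-atom" RMSDs rarely state whether solvent is included, and
solvent placement is the least reproducible part of independently built
models, so waters and ions are excluded by default and `scope = "all"`
reports the alternative rather than guessing intent.

## Bi-ionic selectivity analysis

Under a bi-ionic condition (cation X inside at [X⁺]ᵢₙₜ, cation Y outside at
[Y⁺]ₑₓₜ), the GHK voltage relation reduces to

$$\frac{P_X}{P_Y} = \frac{[Y^+]_{ext}}{[X^+]_{int}}
  \, e^{-E_{rev} F / (R T)}.$$

`estimate_erev()` computes one reversal potential per replicate as the zero
crossing of the I–V curve, linearly interpolated between the bracketing
steps of the −100…+100 mV, 20 mV protocol; the family estimate is the
replicate mean ± SEM, matching the reporting convention of whole-cell
studies. Linear interpolation (not a spline or a GHK current fit) is robust
to the 20 mV step size and cannot overshoot; whether published values come
from interpolation or fitting is usually unstated, and interpolation is the
documented default here. A replicate whose current never changes sign raises
an out-of-range error naming the replicate; multiple crossings raise an
ambiguity error listing them — `selectivity_table()` catches the former and
flags the construct non-functional (the non-transfected-control case)
rather than dropping it.

Temperature defaults to 298.15 K (RT/F ≈ 25.69 mV); recording temperature
is rarely reported for room-temperature whole-cell work, and the quoted
integer ratios (~9 at −55 mV, ~13 at −65 mV) are reproduced anywhere in
293–300 K. No leak or background subtraction is applied — endogenous
currents therefore bias measured selectivity downward, a known limitation
of the whole-cell configuration rather than of the estimator.

## Synthetic data: what it emulates, and what it does not

The generators produce inputs with recorded ground truth (`truth` in every
return value), which is the module's entire test surface.

- `make_toy_channel()` stacks rings of carbon atoms around z, flaring
  parabolically from a central constriction so the analytic minimum pore
  radius **equals** the requested value (default 1.7 Å, the open gate;
  0.5 Å mimics the closed gate). Rings are split between 2 or 4 chains with
  the corresponding rotational symmetry and carry a small seeded twist;
  constriction rings are isoleucine between leucine/serine flanks, so
  hydrophobicity profiling has signal. Pore length defaults to 45 Å, the
  scale of the real pathway.
- `paired_ion_maps()` renders Gaussian density (width 0.8 Å) for the
  structure plus solvent blobs at shared positions — ions on the axis,
  waters off-axis, every pair ≥3 Å apart and exactly on voxel centers of
  the default 64³, 1 Å grid, so peak heights are uniform and connected
  components never fuse. Partner-map ion blobs are scaled by the amplitude
  ratio (default 3); water blobs are equal; each map receives independent
  Gaussian noise (default sd 0.02 of the solvent amplitude, a modest
  residual appropriate to a density-modified map). The recorded per-map
  thresholds are the scenario's operating point: 0.8× the weakest solvent
  peak in the primary map, and the midpoint between the strongest water and
  weakest ion in the partner map.
- `simulate_iv()` inverts the bi-ionic relation for the true reversal
  potential and generates linear currents I(V) = g·(V − E_rev)·(1 + ε) at
  the 11-step protocol, with multiplicative zero-mean noise (default 5%
  relative, 3 replicates, conductance 10 pA/mV). Linear conductance is
  deliberate: the estimator only uses the zero crossing, so GHK current
  curvature would add realism without exercising anything further, and
  multiplicative noise preserves the sign structure the way gain-like
  variability does.

What the generators do **not** model: CTF and radiation-damage noise
spectra, conformational heterogeneity, B-factor variation, scattering-factor
shapes (blobs are Gaussians), liquid-junction potentials or seal leak.
Passing tests therefore demonstrate that the algorithms are correct on data
satisfying their stated assumptions — not that the assignments would survive
every pathology of real micrographs or recordings.

## Problem sizes and determinism

The shipped tests and the acceptance script run the default study-scale
scenarios: 64³ maps, 4 ions + 12 waters, 3-replicate I–V families across
true ratios {1, 3, 9, 13, 36}, and pore profiles of a few dozen planes —
sizes a laptop handles in seconds. Every stochastic stage takes an integer
seed, restores the caller's RNG state, and reproduces byte-identical output
for identical inputs; `run_pipeline()` writes no timestamps so whole report
bundles are byte-reproducible.

## Known limitations

- Orthogonal map cells only; multi-model ensembles and alternate locations
  beyond the highest-occupancy one are not handled.
- Voxel-overlap matching requires both maps on the same grid; superpose
  models (and resample maps) upstream if they are not.
- The profiler's in-plane search is local within `max_offset` of the axis:
  a pore meandering farther than that from the supplied axis needs a better
  axis, not a larger offset.
- Occupancy refinement, solvent B-factor modeling, and automated water
  picking are out of scope; the site table is an assignment, not a model
  build.
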