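---
title: "A discrete-ordinates Boltzmann dose engine for photon and proton beams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A discrete-ordinates Boltzmann dose engine for photon and proton beams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ordose)
```

## The model

`ordose` computes absorbed dose in a voxel phantom by solving the linear
Boltzmann transport equation (LBTE) with the method of discrete ordinates.
Direction space is discretised into a small set of ordinates labelled by
gantry and couch angles; energy is discretised into multigroup bins with a
flat within-group spectrum, so the group fluence equals the group-integrated
continuous fluence exactly.  The transport equation is solved by source
iteration: the scatter source is accumulated from the current fluence, a
transport sweep propagates it through the grid in the upwind (octant) order
of each ordinate, and the cycle repeats — five times by default, which for
photons corresponds to five scattering generations per particle.

The spatial closure is a hybrid: the cell-centre update uses the
diamond-difference coefficients `2|mu|/dx` etc., while the outflow faces are
set equal to the centre value (step scheme).  The inflow of the next cell
therefore equals the centre of the previous one, and a single octant-ordered
pass solves each group exactly for fixed sources.  Boundaries are vacuum
(zero inflow).

Three particle stages are chained:

* **Photons** stream from a dual-source accelerator head model as an
  analytic unscattered fluence (inverse square, error-function aperture
  penumbra, spectrum, exponential attenuation over the radiological depth),
  distributed over the four ordinates surrounding the beam direction by
  bilinear fractions.  Compton scattering (Klein–Nishina, with the
  kinematic initial-energy matrix collapsing the double scatter integral to
  one sum) generates the scattered fluence.
* **Electrons** receive a fixed source from Compton recoils of the full
  photon fluence and are transported with Møller (collision) and Mott
  (elastic nuclear) scattering.  Dose is the ordinate-summed electron
  fluence times the electron mass collision stopping power.
* **Protons** are treated with a continuous-slowing-down (CSDA) fixed
  source: each energy layer's residual energy along the radiological depth
  axis follows the recursive energy-loss map, the fluence carries an
  inverse-square factor and the loss term `1 - lambda z - tau sigma_Mott`,
  and only elastic (Mott) scattering is left to the LBTE.  Dose is fluence
  times the proton stopping power at the group energies.

The analytic comparator builds spread-out Bragg peaks (SOBPs) from
closed-form pristine curves of the Bortfeld family with a three-point
range-straggling average, `D(r) = [d(r-Δ) + d(r) + d(r+Δ)]/3`, `Δ = 1 mm`.

## Parameters that matter

| Parameter | Default | Units | Role |
|---|---|---|---|
| quadrature | 4 couch × 8 gantry | — | 26 distinct weighted directions; fine variant 18 × 36 with sine weights |
| photon groups | 0.5–4 by 0.5, 5–10 by 1 | MeV | 14 groups; electrons reuse this grid |
| proton groups | 5–250 by 5 | MeV | 50 groups |
| `f_C0, f_C, f_Ctot` | 2.0, 10.0, 3.0 | — | empirical Compton factors compensating the coarse quadrature |
| `f_M`, `f_Mott_w`, `f_Mott_m` | 8e-5, 8e-3, 10.0 | — | electron total corrections |
| `f_low`, `f_high` | 0.8, 0.05 | — | energy-dependent proton Mott reduction |
| `lambda` | 5e-4 | 1/mm | nuclear fluence loss per radiological path |
| `tau` | 1e-3 | — | elastic fluence-loss coefficient |
| iterations | 5 | — | transport sweeps (overridable) |
| voxel grid | 2.5 | mm | native resolution; desk benchmarks use 5–10 mm |
| adaptive thresholds | 20% / 5% | of max fluence | photon / proton 4×4×4 cluster merging |
| `Δ` (straggle) | 1.0 | mm | three-point averaging shift |
| `alpha`, `p` | 0.0022 cm, 1.77 | — | range–energy relation `R = alpha E^p` |

## Numerical choices and calibrations

**Units.**  Compton and Møller cross sections are microscopic (mm² per
electron) and pair with absolute electron densities (electrons/mm³); Mott
cross sections are macroscopic water-referenced (1/mm at 1 g/cm³) and pair
with relative core densities.  Products in the transport equation are then
macroscopic coefficients in 1/mm throughout.

**Mott screening calibration.**  The empirically corrected totals pair
stated correction factors with theoretical cross sections whose absolute
normalisation the source material does not print.  We use the
screened-Rutherford form with Molière/Thomas–Fermi screening scaled by a
per-particle factor fixed once by physical anchors: for electrons the
corrected water total at 1 MeV equals the reciprocal CSDA range (fluence
attenuates on the range scale — the removal term stands in for continuous
slowing down, which this model does not carry explicitly); for protons the
elastic-loss term `tau * sigma_tot` reaches 0.05 in the lowest (5 MeV)
group, so the term stays well inside the ~2% plateau agreement band at
plateau-relevant residual energies and concentrates in the final
millimetres of range — the stated behaviour of `tau`.  Both scale factors
come out of order unity.

**Scattering-channel balance.**  A coarse quadrature samples a differential
cross section at a handful of cosines, so the discrete in-scatter sum and
the (empirically corrected) removal total need not balance.  Three
consequences are handled explicitly:

* Møller differentials are renormalised so each source ordinate/group's
  summed in-scatter equals its corrected total — otherwise the channel
  creates particles (removal is scaled by 8e-5, the differentials are not)
  and source iteration diverges.
* Electron groups whose CSDA range is below the native voxel size
  (the 0.5 MeV group at 2.5 mm) are absorption-only: a sub-voxel range
  cannot be transported on the grid, and with the printed factors that
  group would otherwise be super-critical (in-scatter/removal ≈ 1.5).
  With this cutoff, photon and electron probe fluences in water, lung and
  bone all settle within 1% by iteration five.
* The lowest photon group's in-scatter slightly exceeds its removal
  (ratio ≈ 1.2, from the large-angle factor 10 versus total factor 3), but
  down-scatter and spatial leakage keep the photon stage convergent.

**Proton group assignment by path fraction.**  Near the end of range the
residual energy crosses several 5 MeV groups inside one voxel.  A voxel's
unscattered fluence is therefore split across groups in proportion to the
radiological path length spent in each group inside the voxel (an exact
interval overlap on the depth–energy table).  Point-sampling the voxel
centre instead aliases against the 1 mm layer-range comb with a ~100 mm
beat period; the artefact measured ~5% of local dose before this fix.
Residual energy below the lowest boundary (2.5 MeV) deposits locally as
equivalent group-1 fluence (energy conservation; the spec's cutoff rule).

**Range anchoring.**  Residual-energy tables integrate the Bethe stopping
power with midpoint steps, then rescale the depth axis so each layer's
range equals the nominal `csda_range()` value, with the reciprocal factor
on the scored fluence (energy conserving).  This commissions every layer to
its nominal range — as measured beam data would — and keeps the engine and
the analytic comparator on one range–energy calibration.  Without it the
two disagree by 1–2 mm in range, the analogue of the ~3 mm range
overestimate reported for the original 2.5 mm implementation.

**Analytic comparator loss model.**  The comparator is a modified Bortfeld
curve.  Its default fluence-loss factor is `1 - lambda r` with the
transport engine's `lambda`, and none of the lost energy is redeposited
locally (`gamma = 0`), because the engine's `lambda` term removes fluence
without depositing its energy; comparing against a comparator that
redeposits 60% of it would measure nuisance-model differences, not
transport.  The classical parameterisation (`beta = 0.012` /cm,
`gamma = 0.6`) remains available through arguments.  Pristine curves carry
the Gaussian range-straggling width `sigma = 0.012 R^0.935` cm before the
three-point average.

**SOBP weights.**  Layer weights are the bin integrals of the power-law
weight density `w(R) ∝ (Rmax - R)^(-1/p)`, which is exactly flat for the
power-law stopping kernel; the stated `(d/R)^0.7` correction multiplies
each layer's weight by `(R_layer/R_max)^0.7` (the evaluation point is not
printed; this reading is adopted and documented).  The correction targets
measured depth-dose input and tilts a purely analytic superposition towards
the distal end, so the flatness property is asserted for the uncorrected
weights on the loss-free kernel (±3% about the plateau mean), while the
stated corrected weights are used for all benchmark comparisons — they
appear identically on both sides.

**Ties and determinism.**  The uncertainty kernel's top-64 selection breaks
probability ties by lexicographic offset order; the pipeline contains no
randomness, and identical configurations give byte-identical CSV outputs.

## What the synthetic world does and does not establish

Phantoms are water-equivalent scaled (relative electron and core densities
equal the relative mass density), homogeneous or with a single rectangular
inhomogeneity; the photon spectrum is a plausible synthetic 6 MV table and
the attenuation table is a standard water tabulation.  The benchmarks
reproduce the validation geometry (100 × 100 mm fields, SSD 850 / 2150 mm,
SOBP 100–200 mm) at a 5–10 mm desk-scale grid instead of 2.5 mm, and the
convergence studies use 10 mm.  A green suite therefore establishes the
transport machinery, its conservation and convergence properties, and
engine-versus-analytic consistency at desk scale — not absolute dosimetric
accuracy against measured beam data, vendor commissioning, or clinical
anatomy (HU heterogeneity beyond the synthetic ladder).  The proton
elastic stage converges to machine precision within three iterations here
because the calibrated elastic totals are strongly absorbing; the original
implementation's slower, visibly evolving convergence traces reflect a
different (unprinted) cross-section balance.

## Known limitations

* No photoelectric or pair-production interactions (per the source model);
  avoid beams entering through metal.
* Electron transport uses discrete Møller/Mott collisions, not multiple
  scattering theory; the sub-voxel-range cutoff deposits 0.5 MeV electrons
  locally.
* Off-axis spectral softening defaults to zero; monitor-unit calibration is
  out of scope (relative layer weights only).
* The adaptive 4×4×4 merging is defined for the 2.5 mm native grid; at
  coarser desk grids the merged cells are proportionally larger and the
  scheme degrades away from the unmerged region.
* Proton arcs are supported only as configuration sugar (per-segment layer
  lists); no magnetic fields, no Krylov acceleration, no GPU path.
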