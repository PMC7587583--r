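---
title: "Modelling capacitively coupled electrical stimulation of cell-laden conductive hydrogels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling capacitively coupled electrical stimulation of cell-laden conductive hydrogels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capstim)
```

## The physical problem

Capacitive coupling delivers an alternating electric field to a biological
sample without galvanic contact: two glass cover slips insulate the
electrodes from a thin layer of cell culture medium, so only displacement
currents drive the sample. The quantity believed to mediate the biological
response is the induced transmembrane potential (TMP) of the cells — the
potential difference across the plasma membrane — because changes in the
TMP gate voltage-sensitive ion channels. When the cells sit on or inside an
electrically conductive hydrogel scaffold, the scaffold's conductivity and
permittivity reshape the local field and hence the stimulation.

`capstim` models this system at three levels: an analytic equivalent
circuit of the layered chamber, an axisymmetric electro-quasistatic
finite-element (FEM) solution including hydrogel and single cells, and
spherical multi-shell dielectric cell models for dielectrophoresis
estimates. All three plug into a common uncertainty-quantification layer.

## Equivalent circuit

Every layer is a lossy dielectric with complex permittivity
$\varepsilon^* = \varepsilon_r\varepsilon_0 - i\sigma/\omega$
(time convention $e^{+i\omega t}$, so $\mathrm{Im}\,\varepsilon^* \le 0$
for passive materials), and, as an ideal parallel-plate element, impedance
$Z = d/(i\omega\varepsilon^*\pi r^2)$. The chamber is the series sum
$Z_\mathrm{total} = 2Z_{cs} + Z_{buf}$ and acts as a voltage divider, so
the field in the medium is
$E_s = (V_0/d_{buf})\,Z_{buf}/Z_\mathrm{total}$, with $V_0$ interpreted as
the *amplitude* (not RMS) of the applied voltage. With the reference
geometry (cover slips $d_{cs} = 0.15$ mm, $r_{cs} = 16.5$ mm,
$\varepsilon_r = 4$; medium $d_{buf} = 1.415$ mm, $\sigma = 1.5$ S/m,
$\varepsilon_r = 80$; $V_0 = 44.81$ V) the package computes
$|E_s| = 1.33$ V/m at 60 kHz — 1.5 times below the value traditionally
assumed for this device class. Because the cover slips dominate
$Z_\mathrm{total}$, both $|Z| \propto 1/f$ and $|E_s| \propto f$ hold
throughout the capacitive band (below roughly 1 MHz), and the ohmic power
deposited in the medium stays near 3 µW, far too small for thermal
effects.

## Electro-quasistatic finite elements

Below 100 MHz at centimetre scale, wave and inductive effects are
negligible and Maxwell's equations reduce to
$\nabla\cdot(\kappa\nabla\varphi) = 0$ with the complex admittivity
$\kappa = \sigma + i\omega\varepsilon_r\varepsilon_0$. The chamber is
rotationally symmetric, so the package solves on a triangulated $(r, z)$
half-plane with the axisymmetric weight $2\pi r$. Capacitive coupling is
imposed exactly as in the experiment description: the electrodes are not
meshed; instead $\varphi = V_0$ on the outer face of the top cover slip,
$\varphi = 0$ on the bottom one, zero normal current elsewhere, and the
natural condition on the axis.

Design choices that matter:

* **Element order.** Linear (P1) triangles on graded meshes. For the
  layered validation chamber the exact solution is piecewise linear in
  $z$, hence *inside* the P1 space: the computed impedance and field
  match the circuit to machine precision, and the validation comparison
  tests the assembly, boundary conditions and current extraction rather
  than mesh-resolution luck. For cell scenarios the mesh is refined until
  the 0.5%-per-refinement-step convergence target holds (see below).
* **Membrane as a thin-layer interface.** Meshing a 7 nm membrane inside
  a 35 mm chamber is infeasible (five orders of magnitude). The membrane
  curve instead carries duplicated node pairs; inner and outer copies are
  coupled through the surface admittance
  $Y_m = (\sigma_m + i\omega\varepsilon_m\varepsilon_0)/d_m$ via the
  interface term $\int Y_m (\varphi_{in}-\varphi_{out})
  (v_{in}-v_{out})\,2\pi r\,ds$. The potential jump across a pair is the
  TMP itself — no post-processing approximation. A volumetrically
  resolved membrane is deliberately not offered; the thin-layer model is
  validated against the analytic oracle below.
* **Meshing.** Tensor-product graded grids for the layered regions; an
  O-grid around the cell (polar core inside the membrane, transfinite
  transition ring from the membrane curve to a rectangular hole cut from
  the tensor grid). Element sizes grow geometrically (ratio 1.4) from
  about 1 µm at the membrane to about 1.4 mm at the chamber rim; a
  refinement level halves all target sizes. The base level places at
  least 8 elements across the cell radius.
* **Linear algebra.** The complex system is solved as its real 2×2 block
  form with a sparse direct factorisation (`Matrix`), re-assembled from
  cached per-region stiffness matrices at each frequency, so sweeps and
  material studies pay the geometric cost once.
* **Current and impedance.** $Z = V_0/I$ with $I$ the sum of discrete
  reaction forces on the electrode nodes — the superconvergent flux for
  this discretisation. Top and bottom currents agree to ~1e−10 relative,
  which the tests assert at 1e−8.

### Validation oracle

For a spherical cell in a uniform field, the first-order membrane-charging
model gives
$\Delta\Phi = 1.5\,E R_c\cos\theta/(1 + i\omega\tau)$ with
$\tau = R_c (\varepsilon_m\varepsilon_0/d_m)(1/\sigma_{cyt} +
1/(2\sigma_{med}))$. The toy-box fixture (100 µm cylindrical box, 5 µm
cell) compares the FEM TMP against this closed form across
10 Hz–100 MHz. The fixture sets the *bulk* relative permittivities of
medium and cytoplasm to 1 while keeping the membrane at its physiological
capacitance: the closed form neglects bulk displacement currents, which at
100 MHz would otherwise contribute ~20% themselves — the fixture is
designed inside the oracle's validity region so that disagreement means
solver error, not oracle error. The observed agreement is ~1% across the
band (asserted at 5%).

## Cell placements

Four single-cell configurations mirror the stages of a scaffold
experiment: an oblate adherent cell near the bottom cover slip (the 2D
culture benchmark), the same cell resting on the hydrogel surface, a
spherical cell straddling the hydrogel–medium interface (half grown-in),
and a spherical cell centred in the scaffold. The oblate semi-axes
(10 × 2.5 µm) and the spherical radius (7 µm, mid-range for eukaryotic
cells) are configuration defaults, not measured values. Two placement
details are genuine design decisions:

* the adherent benchmark cell sits one radial semi-axis (10 µm) above the
  glass. An insulating wall directly at the membrane skews the
  apex-versus-bottom comparison (the asymmetry decays from ~22% at 2.5 µm
  stand-off to ~3% at 10 µm); the benchmark is meant to probe the cell in
  the locally uniform field, where apex and bottom polarise equally.
* the cell resting *on the hydrogel* touches the gel surface at its
  bottom pole, so the lower membrane hemisphere is genuinely exposed to
  the scaffold — which is what makes its TMP sensitive to the gel
  conductivity.

## Hydrogel physics the model reproduces

With the hydrogel block (1 mm radius × 1 mm height on the bottom cover
slip) the solver reproduces, from first principles, the field partition
$\sigma_{hydro} \gtrless \sigma_{buf} \Rightarrow E_i \lessgtr E_o$, the
insensitivity of the total chamber impedance to the gel (the scaffold
occupies <1% of the cross-section, which is why impedance spectroscopy
cannot monitor it in situ), the monotone decrease of an embedded cell's
TMP with gel conductivity, and the TMP rise only above ~100 kHz.

The pole-to-equator field ratio quantifies the squeezing force direction
on an embedded cell. Its deformation study uses gel conductivities
{1.5, 3, 5.5, 10} S/m — from medium-matched up to the 10 S/m boundary
case, the range in which the characteristic spectra (ratio ≤ 1, peak
approaching 1 near 10 MHz for the least conductive gel, no considerable
increase for the most conductive one) are physically attainable: for a
gel *less* conductive than the cytoplasm (1.5 S/m) the pole field would
exceed the equatorial field in the conduction-dominated band and the
ratio would pass well beyond one.

## Multi-shell cells and dielectrophoresis

The Clausius–Mossotti factor
$CM = (\varepsilon_2^* - \varepsilon_1^*)/(\varepsilon_2^* +
2\varepsilon_1^*)$ needs the equivalent homogeneous permittivity
$\varepsilon_2^*$ of the cell. The package composes it from the standard
single-shell reduction
$\varepsilon_{eq} = \varepsilon_{sh}(\gamma^3 + 2W)/(\gamma^3 - W)$,
$\gamma = R/(R-d)$, $W = (\varepsilon_{in} - \varepsilon_{sh}) /
(\varepsilon_{in} + 2\varepsilon_{sh})$: nucleoplasm coated by the
nuclear envelope, homogenised into the cytoplasm by Maxwell–Garnett
mixing at volume fraction $(R_n/(R_c-d_m))^3$ (for concentric geometry
this is algebraically identical to a cytoplasm shell), then coated by the
membrane. Whether the nucleus belongs in the dielectrophoresis model is
not obvious a priori, so both modes are exposed
(`cm_uq_model(include_nucleus = )`); the low-frequency response is
insensitive to the choice. The test suite checks the whole chain against
an independent oracle that solves the concentric-multishell Laplace
boundary-value problem as a linear system — agreement is ~1e−13, asserted
at 1e−10.

Under the hydrogel and eukaryotic-cell parameter distributions the mean
real CM factor stays negative across the band (cells are pushed towards
low-field regions, e.g. away from a less-conductive gel), with positive
excursions of the 95th percentile only in the megahertz window. The
computed zero crossing of that upper bound sits near 0.5 MHz, slightly
below the nominal 1 MHz edge of the window; the tests therefore assert
the claim at decade granularity (negative through 100 kHz, positive
somewhere in 1–100 MHz, negative again at 100 MHz).

## Uncertainty quantification

Inputs are independent uniforms: geometry ±10% around the printed means,
material properties from the tabulated ranges (hydrogel conductivity
U(0.1, 2.0) S/m and permittivity U(60, 1000); medium U(0.5, 1.5) S/m and
U(60, 80); membrane, cytoplasm and nuclear compartments from the
eukaryotic-cell tables). The cover-slip permittivity, for which no range
is printed, follows the ±10% geometry convention. Two propagation routes:

* **Monte Carlo** on a Saltelli design: a budget of $n$ evaluations is
  split into base blocks A, B and the pick-one columns $AB_i$, so 40,000
  calls for six parameters corresponds to a base sample of 5,000.
  First-order indices use the Saltelli-2010 numerator estimator;
  prediction intervals are pointwise 5th/95th percentiles (linear
  interpolation) of the A∪B evaluations.
* **Point-collocation polynomial chaos**: least-squares regression onto
  the total-degree orthonormal Legendre basis, with the sampling plan
  sized at twice the number of basis terms plus two —
  $2\binom{n+p}{p}+2$, i.e. 422 evaluations for six parameters at the
  default order $p = 4$ (the order is inferred from that evaluation
  count and is configurable). Moments and Sobol indices come from the
  coefficients; intervals from cheap surrogate resampling.

Everything is seeded: identical study + seed gives bit-identical results,
which the command-line layer extends to byte-identical CSV output.

The circuit impedance study shows Sobol indices that are flat in
frequency and dominated by cover-slip radius, thickness and permittivity.
For the field in the medium this implementation ties the medium radius to
the cover-slip radius (the printed geometric assumption), which removes
the radius-cancellation degeneracy and leaves the medium conductivity as
the dominant field uncertainty; treating the medium radius as a separate
uncertain parameter would redistribute part of that variance to it.

The full-FEM uncertainty study over all tabulated distributions at
polynomial order 4 on the 61-point grid is an overnight computation. The
packaged scaled-down counterpart (three most influential parameters —
gel conductivity, membrane permittivity, cytoplasm conductivity — order
2, three frequencies, 22 FEM evaluations per frequency) preserves the
structure of the result: a prediction interval spanning more than a
factor of three and a TMP that rises sharply above 100 kHz. Its computed
interval reaches a few tenths of a millivolt at 10 MHz; under this drive
voltage the first-order charging bound
$1.5|E_s(f)|/( \omega\,C_m(1/\sigma_{cyt}+1/(2\sigma_{hydro})))$ caps the
apex TMP at millivolt order for every tabulated parameter corner, so
tens-of-millivolt interval widths are not reachable within these study
conditions.

## Problem sizes and determinism

The test suite solves the layered chamber on ~350-node meshes (where the
discretisation is exact), the toy box on ~1,000 nodes, and the cell-laden
chamber on ~3,000 nodes; refinement-level-1 meshes double the resolution
for the convergence checks. Monte Carlo studies in the tests use
2,400–16,000 evaluations and polynomial chaos its standard 422 (or fewer
for reduced parameter sets). All random draws derive from explicit seeds.

## What the synthetic scenarios do and do not show

The scenario generator emulates the printed experimental conditions:
ideal concentric geometry, homogeneous isotropic materials with
frequency-independent intrinsic properties, a single cell, and uniform
parameter uncertainty. It does not emulate electrode electrochemistry,
material dispersion (Debye/Cole–Cole), membrane nonlinearity or
poration, multi-cell interactions, the fibrous microstructure of real
scaffolds, or chemical cell–gel coupling. Passing tests therefore
demonstrate the correctness of the solvers and the stated circuit-level
and single-cell physics — not biological effect sizes.

## Known limitations

* Ellipsoidal Clausius–Mossotti factors (depolarisation factors) are out
  of scope; the CM model is spherical, and the FEM handles oblate shapes
  geometrically instead.
* The full chamber periphery (plastic lid, air gap) is reduced to an
  optional dish ring; the validation scenario is the parallel-plate
  region, which the reference results show is sufficient.
* 3D, non-axisymmetric configurations and cell populations are not
  supported.
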