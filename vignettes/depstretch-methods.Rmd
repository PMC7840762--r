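---
title: "Methods: Maxwell-stress modelling of dielectrophoretic cell stretching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Maxwell-stress modelling of dielectrophoretic cell stretching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A cell suspended between two coplanar microelectrodes polarizes in the
applied AC field. When its permittivity differs from the medium's, the
Maxwell stress carried by the field jumps across the cell boundary and the
resulting surface traction stretches the cell. The steady elongation encodes
a combination of the cell's electrical contrast and its mechanical
compliance; measuring it against a calibrated model turns a DEP chip into a
label-free single-cell mechanical probe. `depstretch` implements the full
chain: chip electrostatics, Maxwell-stress traction, elastic deformation,
the lumped elongation law used to reduce experiments, electrode-design
optimization, and trajectory reduction for measured (or synthetic) data.

## Electrostatics of the chip plane

The model is two-dimensional, in the plane of the electrode surface (top
view) with unit out-of-plane depth. We solve

$$\nabla\cdot(\varepsilon\,\nabla\Phi) = 0,$$

with relative permittivity $\varepsilon_c$ inside the cell disk and
$\varepsilon_m$ outside, Dirichlet values $\Phi = \pm V/2$ on the two
electrode footprints ($V$ is the peak-to-peak drive) and homogeneous Neumann
conditions on the outer boundary. The discretization is a finite-volume
scheme on a graded tensor-product grid: uniform spacing $h = R/n_R$ over a
core box containing the cell and the gap ($n_R$ cells per cell radius,
default 20), geometric coarsening (ratio 1.25) out to the domain boundary.
Faces cut by the cell boundary use a one-dimensional harmonic sub-grid
average of the two permittivities weighted by the intersection fraction, so
the normal flux sees the interface at its true position. The sparse
symmetric system is solved directly (Cholesky via the Matrix package).

Numerical safeguards, each covered by a test:

* the discrete maximum principle ($\Phi$ within the electrode potentials);
* exact linearity in $V$ (so elongation is exactly $\propto V^2$);
* a domain-doubling check showing the Neumann truncation at total extent
  $4(w+d)$ changes the elongation by less than 1%;
* a dielectric cylinder between parallel plates (the 2-D analogue of the
  classical sphere-in-uniform-field validation): the interior field
  magnitude $2\varepsilon_m/(\varepsilon_m+\varepsilon_p)E_0$ is reproduced
  within 2% at the default resolution.

### Interface sampling

The stress jump needs one-sided fields on the cell boundary. Raw one-sided
estimates are obtained by bilinear sampling on two rings per side (1.5 and 3
fine cells away; the outer rings are additionally capped to a third of the
electrode clearance for near-gap-filling cells) and linear extrapolation to
the interface. The raw pairs are then *reconciled* with the exact interface
conditions — the tangential field and the normal displacement
$\varepsilon E_n$ are continuous — by averaging the two one-sided estimates
of each continuous quantity and rebuilding both sides from them. Without
this step the stress jump, a near-cancellation of two $O(\varepsilon E^2)$
terms, amplifies a 3% field error into a ~25% traction error; with it the
traction harmonics are accurate to ~2%. The raw samples are retained in the
solution object, and the continuity defect measured on them is the
discretization diagnostic used in the tests.

### Admissible geometries

The plane model represents the channel mid-height; a cell disk that touches
or overhangs an electrode footprint leaves its domain of validity (the
in-plane Dirichlet region would clamp the potential inside the cell, and the
traction on the covered arc is not representable). `build_geometry()`
therefore rejects disks that touch an electrode. For the default study
ranges this excludes only the largest cells at the smallest gap
(e.g. $R = 12\,\mu m$ at $d = 20\,\mu m$).

## Maxwell-stress traction and elastic response

With the in-plane field $E$ the Maxwell stress tensor is
$\sigma_{ij} = \varepsilon(E_iE_j - \tfrac12\delta_{ij}|E|^2)$; its jump
across the interface gives the surface traction evaluated station-wise on
the boundary. Real permittivities at the drive frequency are used (the
single-shell cell model supplies the frequency dependence of the effective
cell permittivity); the printed form of the traction with complex
permittivities multiplying real field products does not define a real
traction, so the real-part convention is a documented choice here. The
default reports the peak-of-cycle traction computed from amplitude fields;
an `rms` option applies the AC time-average factor 1/2. Either convention is
absorbed into the lumped parameter $S$, so fitted quantities do not depend
on it.

The cell is a linear-elastic disk (Young's modulus $E$, default 0.1 kPa;
Poisson ratio defaults to 0.49, nearly incompressible, in plane stress —
the ratio is not identifiable from the experiments the model serves, so it
is explicit and configurable). The traction is first stripped of its
rigid-body resultants: the force-carrying part of the $n=1$ Fourier
harmonics and the uniform torque mode are projected out exactly
(self-equilibrated $n=1$ deformation modes are kept). The elastostatic
problem is then solved in closed form by a Michell (Airy stress function)
series: per harmonic the $r^n$ and $r^{n+2}$ stress functions match the
boundary traction, $n=0$ is the Lame solution, and displacements follow from
the standard Kolosov formulas. The series is exact for band-limited
tractions, so the elastic stage adds no discretization error. It is checked
against the Lame closed form, against an independent Hooke-consistency test
(numerically differentiating the displacement field and comparing boundary
stresses with the imposed traction), by Betti reciprocity between load
cases, and end-to-end against the fully analytic cylinder-in-uniform-field
elongation.

Elongation is reported as the tip displacement along the inter-electrode
axis averaged over both tips, $L^* = u_{tip}/R$; the model is one-way
coupled (forces from the undeformed geometry), making $L^*$ exactly
proportional to $V^2$ and to $1/E$. Configurations with $|u|/R > 0.2$ emit a
small-strain warning: the linear model is then an extrapolation.

## The lumped elongation law

All geometry dependence is tabulated once by simulation as the
dimensionless factor $\gamma(R, d, w)$, normalized to 1 at a reference
configuration; because of the exact $V^2$ and $1/E$ scalings the table is
independent of the drive and stiffness used to generate it (tested). The
shipped table covers $R \in \{4,6,8\}$, $d \in \{20,45,70\}$,
$w \in \{10,30,50\}\,\mu m$ at $n_R = 16$ with provenance in its header.
Interpolation is trilinear in $\log\gamma$ over $(R, \log d, \log w)$:
$\gamma$ falls off roughly as a power of the gap, and log-space
interpolation keeps the off-grid error at a few percent where plain
trilinear on the same sparse grid errs by tens of percent (a plain-linear
mode is available).

The lumped law $L^* = S\,V^2\,\gamma(R,d,w)$ is fitted by least squares
through the origin on $x = V^2\gamma$; per-cell fits and per-type summaries
accompany the pooled estimate (pooling is the default aggregation; both are
reported since the choice is not dictated by the data model). $S$ carries
units of $1/V^2$. When a contrast and exponent are supplied the mechanical
factor $D = S/\Delta\varepsilon^\alpha$ is also reported.

### The contrast exponent, honestly

The contrast-exponent study fits a single $\alpha$ such that
$L^*/\Delta\varepsilon^\alpha$ (with
$\Delta\varepsilon = |\varepsilon_m - \varepsilon_c|$, the real-part
difference; the sign is tracked separately) collapses across geometries,
by minimizing the worst-case relative spread over a grid
$\alpha \in [0.5, 1.2]$ with golden-section refinement. On planted power
laws the estimator is exact to the grid refinement (tested).

Applied to this simulator over the full study grid (cells of radius 4-12
um, gaps 20-70 um, widths 10-50 um, cell permittivity 100-160 against
medium 80), the collapse is *poor*: the fitted exponent is about 1.11 at
the coarse study resolution with a worst-case deviation of ~13%. The cause
is visible in the per-geometry slopes: near-uniform-field configurations
(small cell, wide gap) are mildly sublinear in the contrast, while
small-gap configurations where the cell fills most of the gap are strongly
superlinear — as the cell permittivity rises, an increasing share of the
drive voltage drops across the thin medium gaps at the tips, intensifying
the local field (a series-capacitor effect reproducible with a hand
two-capacitor model, which gives local exponents of 1.15-1.3 for a 16 um
cell in a 20 um gap). No single exponent collapses both regimes in this
2-D plane model, so the package reports the fitted exponent and deviation
as computed; a sub-unity exponent with a few-percent collapse emerges only
when the study is restricted to cells small relative to the gap, where the
near-uniform-field regime dominates. The corresponding checks in the test
suite assert the sub-unity expectation and are left failing by design as a
record of this disagreement.

## Electrode-design optimization

The design objective is $1/L^*$ (minimized) over electrode width and gap
within $w \in [5,50]$, $d \in [20,70]\,\mu m$ for each of the six
facing-shape scenarios (rectangular, triangular, elliptical and their
pairings; triangular apex half-angle 30 degrees and elliptical protrusion
ratio 0.5 are configurable conventions, as only the relative ranking is
claimed). The optimizer is a real-coded genetic algorithm — population 20,
10 generations, tournament selection of size 3, blend crossover (rate 0.9),
Gaussian mutation (rate 0.2, step 10% of range), one elite, clipping to
bounds — fully reproducible under a seed, with memoized objective
evaluations at coarse solver resolution ($n_R = 8$, chosen by the
mesh-independence ladder at a relaxed 2% tolerance so a full run stays
around 160 simulator calls and well under a minute).

Findings, each reproduced by the seeded tests: the best objective is
monotone non-increasing (elitism) and changes by far less than 1% after the
ninth generation; the gap is driven to its 20 um lower bound; rectangular
pairs beat every other shape pairing, and the ranking is invariant to the
drive voltage. The width behaves differently from the monotone expectation:
elongation grows with $w$ throughout $[5,50]$ at the default 45 um gap, but
at the optimal 20 um gap it saturates once the facing edge is about the
gap-plus-cell scale and is then flat to within half a percent (slightly
*decreasing* towards $w = 50$), so the GA settles on the flat ridge near
$w \approx 21\,\mu m$ rather than the large-width corner. The
corner-location check in the test suite is therefore red on the width coordinate
while every convergence and gap claim passes.

## Trajectory reduction and synthetic fixtures

Measured tip trajectories (delimited text, one row per time stamp with
condition metadata and optional voltage on/off phase annotations) are
reduced to steady-state elongations by a trailing-window plateau detector:
window 10 s, relative drift tolerance 2% per window — conventions, since
the experiments only establish that plateaus exist by ~40 s — with a
two-standard-error allowance so tracking noise on weak signals is not
mistaken for drift. On/off cycles are summarized by per-cycle peaks,
recovery fractions $1 - \mathrm{residual}/\mathrm{peak}$ and the
first-to-last peak drop, the quantities behind reversibility statements.

The synthetic generator emulates the study design — three cell types, 16
cells per condition, nine width/gap conditions at a fixed 8 V drive (a
voltage in the reversible-stretching range) — with plateaus planted by the
lumped law, single-exponential rise kinetics (time constants 5/10/30 s for
erythrocyte-, PBMC- and carcinoma-like types; kinetics never enter the
fitted quantities, only plateaus do), unit-mean lognormal cell-to-cell
variation (default CV 5%) and additive Gaussian tracking noise (0.05 um).
Planted per-type radii (4.5, 6, 7.5 um) stay inside the shipped gamma
hull. Everything is driven by one seed. What passing recovery tests show
is that the reduction-plus-fit chain is unbiased and precise under the
model's own noise structure (planted $S$ recovered within 3% at 5% noise,
exact on noiseless data); they cannot show that real cells follow
single-exponential kinetics, that tracking noise is Gaussian, or that a
cell's contrast is frequency-independent — those remain experimental
questions.

## Numerical conventions and limitations

* Units: micrometres for geometry, volts peak-to-peak, Hz, Pa; fields in
  V/m, tractions in Pa, $S$ in $1/V^2$. $\varepsilon_0 = 8.8541878128
  \times 10^{-12}$ F/m.
* Problem sizes: coarse studies use $n_R = 8$ (~10-30k unknowns, ~0.1 s per
  solve), validation and the shipped table $n_R = 16$-20; the reproduction
  script runs 96 simulations plus five GA runs in about half a minute.
* The model is 2-D and one-way coupled: no channel-height effects, no
  electro-osmosis or Joule heating, no geometric nonlinearity at large
  strain, no viscoelasticity; membrane mechanics enter only through the
  effective shell permittivity, not the elasticity.
* Ties and degeneracies: the GA breaks exact fitness ties by population
  order (deterministic under the seed); gamma tables reject non-positive
  entries; out-of-hull interpolation errors unless forced.
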