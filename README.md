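# depstretch

Dielectrophoresis (DEP) stretches a polarizable cell suspended between two
coplanar microelectrodes: the Maxwell stress carried by the electric field
jumps across the cell boundary, and the resulting surface traction deforms
the cell until the elastic restoring stress balances it. Because the steady
elongation mixes the cell's permittivity contrast with its mechanical
compliance, a calibrated model turns a simple DEP chip into a label-free,
microfluidics-compatible probe of single-cell mechanics — the kind of
measurement used to distinguish erythrocytes, peripheral blood mononuclear
cells and circulating tumour cells in one sample.

`depstretch` is a desk-scale simulator and analysis toolkit for this
experiment, for microfluidics and cell-biomechanics researchers:

* **Chip electrostatics** — finite-volume solution of
  ∇·(ε∇Φ) = 0 on the 2-D chip plane with the dielectric cell disk embedded,
  Dirichlet ±V/2 electrodes (rectangular, triangular, elliptical or plate
  faces) and interface-aware field sampling on the cell boundary.
* **Maxwell stress** — the surface traction
  f = ε_m[(E_out·n̂)E_out − ½|E_out|²n̂] − ε_c[(E_in·n̂)E_in − ½|E_in|²n̂],
  net forces, and the dipole-approximation force for cross-checks.
* **Elastic response** — closed-form Michell-series solution of the
  linear-elastic disk under the (rigid-body-equilibrated) traction,
  yielding the normalized elongation L\* = (L − R)/R.
* **The lumped law** — L\* = S · V² · γ(R, d, w): simulation-generated γ
  tables with log-space trilinear interpolation, estimation of the
  permittivity-contrast exponent α by worst-case collapse, and
  least-squares fitting of the cell-type parameter S (units 1/V²) from
  measured elongations.
* **Electrode design** — a seeded real-coded genetic algorithm over
  electrode width and gap, and ranking of the six facing-shape scenarios.
* **Measurements** — reduction of cell-tip trajectories (plateau
  detection, on/off-cycle reversibility), S estimation per cell and per
  type, and a fully seeded synthetic-trajectory generator.

Single-shell cell dielectrics (membrane + cytoplasm), the
Clausius–Mossotti factor, and YAML/JSON configuration files are included.

## Worked example

Simulate the optimization-study setup — an 8 µm diameter cell (ε = 120,
E = 0.1 kPa) in a medium of ε = 80, between rectangular electrodes of
width 50 µm separated by 20 µm, at 10 V peak-to-peak:

```r
library(depstretch)
cfg <- stretch_config(R = 4, eps_m = 80, eps_c = 120, V = 10,
                      w = 50, d = 20, youngs_modulus = 100)
simulate_stretch(cfg)
#> <elongation_result> R = 4 um
#>   u_tip = 1.1153 um, L = 5.1153 um, L* = 0.27882
```

The cell tip moves 1.12 µm outward along the inter-electrode axis, a
normalized elongation L\* of 0.28 (with a small-strain warning at this
drive — elongation scales exactly with V², so halving V gives a quarter of
it). Fit the lumped parameter from a synthetic three-type study (16 cells
per condition, nine width/gap conditions, 5% cell-to-cell noise) using the
shipped geometry-factor table:

```r
tab <- default_gamma_table()
trajs <- synth_trajectories(S_true = c(erythrocyte = 4e-3, pbmc = 2e-3,
                                       t47d = 8e-4),
                            table = tab, seed = 1)
estimate_S(trajs, tab)
#> <lumped_fit> S = 0.0019195 1/V^2 (se 6.4e-05, n = 408, 408 cells)
#>   per type:
#>         type     S_pooled    se_pooled  S_cell_mean    S_cell_se n_obs n_cells
#>  erythrocyte 0.0040308691 1.650656e-05 0.0039910625 1.928158e-05   138     138
#>         pbmc 0.0019897279 7.878216e-06 0.0019937934 1.068791e-05   136     136
#>         t47d 0.0007953376 3.767100e-06 0.0007939897 5.799888e-06   134     134
```

The three planted S values (4e-3, 2e-3, 8e-4 1/V²) are recovered within a
percent and separated by dozens of standard errors — the separation that
makes S usable as a cell-type fingerprint.

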