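# poroperf

Coronary blood flow and myocardial mechanics are tightly coupled: vessel
compression by the contracting or inflating wall changes the resistance to
flow, and vascular filling stiffens the wall (the "garden-hose" effect).
Geometrically explicit network models capture neither effect tractably at
organ scale. `poroperf` implements the continuum alternative for
researchers in cardiac biomechanics and perfusion modelling: the myocardium
as an **incompressible multi-compartment poroelastic medium** at finite
strain, with its parameters derived from a discrete vascular network.

## What it computes

Each functional group of vessel calibres is a fluid compartment `i` with
porosity φᵢ, pressure field pᵢ and permeability tensor Kᵢ, coexisting
pointwise inside the solid skeleton (Σᵢ φᵢ + φₛ = 1). On the reference
configuration (deformation gradient F, J = det F, fluid mass increases mᵢ
per reference volume):

* Darcy flow and mass balance per compartment:
  `F Mᵢ/ρf = −J Kᵢ F⁻ᵀ ∇pᵢ`,
  `dmᵢ/dt + ∇·Mᵢ = −Σₖ J βᵢₖ (pᵢ − pₖ) + ρf qᵢ`,
  with a symmetric, zero-diagonal exchange matrix β (mass-neutral by
  construction) and optional restriction to strictly hierarchical coupling
  (`make_hierarchical()`).
* Finite-deformation equilibrium `∇·(F S) = 0` under the volume constraint
  `J = 1 + Σᵢ mᵢ/ρf` (Lagrange multiplier λ), with the exponential
  strain energy
  `Ψ = a [exp(D₁(Ī₁(1+ΣQ₁ᵢmᵢ/ρf)−3) + D₂(Ī₂(1+ΣQ₂ᵢmᵢ/ρf)−3) +
  D₃((J−1)² + (ΣQ₃ᵢmᵢ/ρf)²)) − 1]`
  that also yields the pore pressures `pᵢ = ρf ∂Ψ/∂mᵢ − λ`.
* Homogenisation of a discrete tree: perfusion-territory partition by a
  nearest-subtree distance metric, conductance-weighted orientation (PCA)
  permeability tensors `K = (1/V) Σ g L² d̂ d̂ᵀ`, porosities, and a
  topology-derived exchange matrix.
* A Poiseuille network solver (`g = πr⁴/8μL`, Kirchhoff conservation) as
  the discrete ground truth, plus a seeded synthetic coronary-tree
  generator standing in for imaged anatomy.
* P2/P1 tetrahedral finite elements, backward Euler, and a partitioned
  fixed-point fluid–solid coupling (compiled assembly kernels via Rcpp).

The methods vignette (`vignettes/multicompartment-perfusion.Rmd`) documents
the model, the numerical choices and the limitations.

## Worked example: discrete network versus continuum

```r
library(poroperf)
report <- run_network_comparison(comparison_config(seed = 1))
round(report$slabs, 2)
#>   slab mid discrete full hierarchical
#> 1    1   3     8.59 7.80         7.81
#> 2    2   9     7.61 6.08         6.11
#> 3    3  15     6.24 4.82         4.83
#> 4    4  21     6.28 4.76         4.79
#> 5    5  27     5.30 4.38         4.41
round(report$max_rel_err, 3)
#> [1] 0.177
c(report$max_pressure_full, report$max_pressure_hier)
#> [1] 9.9297 9.9309
```

A seeded 641-segment arterial tree (radii 0.14-1 mm) is grown through a
14 x 14 x 30 mm block of tissue; Poiseuille flow is solved between a
10 kPa arterial root and 3 kPa terminal reservoirs, the tree is
homogenised into a three-compartment Darcy model driven by the same two
pressures, and both pressure fields are volume-averaged on five axial
slabs (values in kPa). The continuum tracks the discrete solution within
18 % of the peak slab pressure here, and the strictly hierarchical variant
over-estimates the pressure (9.9309 vs 9.9297 kPa at the inlet, and in
every slab above) because this tree contains direct large-to-small vessel
connections (`report$has_direct_13`) whose removal lowers the overall
permeability.

The second experiment, `run_passive_inflation(inflation_protocol())`,
inflates an annular wall to 1.5 kPa with and without a perfusion source
ramped to an 8 % wall-volume increase; the perfused wall ends with the
smaller cavity volume — perfusion stiffens the ventricle — and the
compliance series quantifies it.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/perfusion.R gen-tree --config tree.yaml --seed 1 --out out/
Rscript inst/cli/perfusion.R compare-network --config cmp.yaml --out out/
```

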