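---
title: "Multi-compartment poroelastic modelling of coronary perfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment poroelastic modelling of coronary perfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poroperf)
```

## The model

Myocardium is treated as a saturated porous medium: an incompressible
solid skeleton of volume fraction $\phi_s$ interpenetrated by $N$ fluid
compartments, each a functional group of vessel calibres (large arteries,
arterioles, capillaries) with its own porosity $\phi_{f,i}$, pressure field
$p_i$ and permeability tensor $K_i$, with
$\sum_i \phi_{f,i} + \phi_s = 1$. Treating vessel scales as separate,
pointwise-coexisting compartments preserves the hierarchy of flow between
nearby vessels of very different calibre, which a single-compartment Darcy
model would smear out.

All fields live on the reference (undeformed) configuration. With
deformation gradient $F$, Jacobian $J$, and fluid mass increases $m_i$
(mass per reference volume), each compartment obeys a Lagrangian Darcy law
and mass balance

$$F M_i/\rho_f = -J K_i F^{-T} \nabla_X p_i, \qquad
\frac{d^s m_i}{dt} + \nabla_X \cdot M_i =
 -\sum_k J\,\beta_{ik}(p_i - p_k) + \rho_f q_i,$$

where $M_i$ is the Lagrangian mass-flux vector, $q_i$ a volumetric source
(1/s) and $\beta_{ik}$ a symmetric, zero-diagonal exchange matrix: mass
moves between compartments in proportion to their local pressure
difference, and symmetry makes the exchange exactly mass-neutral.
Eliminating $M_i$ gives the form actually advanced in time; the flux is
recovered once per converged step.

The skeleton is governed by finite-deformation equilibrium
$\nabla_X\cdot(FS) = 0$ under the volume constraint
$J = 1 + \sum_i m_i/\rho_f$: the solid matrix itself is incompressible, so
tissue volume changes only by pore fluid accumulation. The constraint is
enforced by a Lagrange multiplier field $\lambda$, and
$S = \partial\Psi^s/\partial E + \lambda J C^{-1}$.

The strain energy is an isotropic exponential law modified by the fluid
mass increases,

$$\Psi^s = a\left[\exp\!\Big(D_1(\bar I_1(1+\textstyle\sum_i Q_1^i
 m_i/\rho_f)-3) + D_2(\bar I_2(1+\sum_i Q_2^i m_i/\rho_f)-3) +
 D_3((J-1)^2+(\sum_i Q_3^i m_i/\rho_f)^2)\Big) - 1\right],$$

with $\bar I_1 = J^{-2/3} I_1$, $\bar I_2 = J^{-4/3} I_2$ the modified
invariants of $C = F^TF$. This grouping is definitional here: it is the
unique arrangement of these terms for which the energy *and* the stress
vanish identically in the reference state ($F = I$, $m = 0$), which the
test suite asserts. Compartment pressures follow from the same energy,
$p_i = \rho_f\,\partial\Psi^s/\partial m_i - \lambda$, using the
identification $m_i = \rho_f (J\phi_{f,i} - \phi^0_{f,i})$, so the law
simultaneously controls skeletal stress and pore-pressure development —
this is the fluid–solid coupling. Note the reference state has a nonzero
pore pressure offset $a(3D_1Q_1^i + 3D_2Q_2^i)$; only pressure
*differences* and gradients drive flow, so the offset is inert.

### Parameters and units

One unit convention is fixed globally: mm, s, g, kPa (so density in
g/mm³ and permeability in mm² kPa⁻¹ s⁻¹ with viscosity absorbed).

| parameter | meaning | default | rationale |
|---|---|---|---|
| $a$ | energy scale (kPa) | 1.0 | manually tuned value for passive myocardium |
| $D_1, D_2, D_3$ | exponent weights (–) | 2.0, 0.2, 2.0 | idem |
| $Q_1^i, Q_2^i, Q_3^i$ | per-compartment mass coupling (–) | 1.0, 0.5, 1.0 | idem; may differ per compartment to capture differing vessel compliances |
| $\rho_f$ | blood density (g/mm³) | 1.05e-3 | physiological |
| $\mu_f$ | blood viscosity (kPa s) | 4e-6 | physiological (4 mPa s) |
| $\beta_{ik}$ | exchange (g mm⁻³ kPa⁻¹ s⁻¹) | estimated from the network | see homogenisation |

## Homogenisation of a discrete tree

`assign_compartments()` thresholds segments by radius (largest vessels =
compartment 1). `partition_regions()` assigns every mesh element to the
feeding subtree nearest its centroid (Euclidean point-to-segment
distance), producing contiguous perfusion territories treated as regions
with zero normal flux. Per (region, compartment):

* **Permeability** `permeability_from_segments()`:
  $K = \frac{1}{V}\sum_s g_s L_s^2\, \hat d_s \hat d_s^T$ — the
  conductance-weighted second-moment (principal-component) matrix of
  segment orientations, with $g_s = \pi r_s^4/(8\mu L_s)$ the Poiseuille
  conductance. The tensor is symmetric positive semi-definite by
  construction. The $g L^2/V$ scaling makes $K$ map a pressure gradient to
  a volume-flux velocity; it is exact for a single straight tube spanning
  the region and composes series chains through the length-weighted mean
  of the per-length conductivity $gL$.
* **Porosity** `compute_porosity()`: total segment cylinder volume over
  region volume.
* **Exchange** `estimate_beta()`: each junction between compartments
  $i<k$ contributes a bridge conductance equal to the series composition
  of half the feeding segment and half the *receiving corridor* — the
  chain of same-compartment segments followed from the junction along the
  largest-conductance child until the compartment changes. The continuum
  fields stand for mid-course compartment pressures, so bulk-to-bulk
  transfer crosses those two half-resistances; using bare junction
  conductances instead ignores the rate-limiting transport inside the
  receiving scale and overestimates transfer severalfold (the analogue of
  the shape factor in dual-porosity models). The estimator is validated
  in the tests against the transfer coefficient implied by the discrete
  Poiseuille solution (flux crossing the $i$–$k$ junctions divided by the
  volume-averaged pressure difference), agreeing within a factor of two.

`make_hierarchical()` zeroes all couplings with $|i-k|>1$, giving the
strictly hierarchical variant in which fluid must pass through
intermediate scales.

## Numerical methods

* **Elements.** Tetrahedra with quadratic (P2) displacement and linear
  (P1) $\lambda$, $p_i$, $m_i$ and $M_i$ — a Taylor–Hood-like pairing that
  stabilises the volume constraint. The element *family* and quadrature
  are this package's choices; only the basis orders are inherited from
  the formulation.
* **Quadrature.** Conical-product Gauss–Jacobi rules on simplices,
  constructed by Golub–Welsch so their exactness is testable to machine
  precision; degree 5 (27 points) for the nonlinear solid terms. A
  degree-4 rule is the minimum that resolved the exponential law in a
  convergence spot-check; the conical construction gives degree 5 at the
  same node count as a tabulated degree-4 rule.
* **Solid solve.** Damped Newton with backtracking line search on the
  residual max-norm (`solve_newton()`). Element residuals are analytic
  (closed-form second Piola–Kirchhoff stress); element tangents are
  assembled by central finite differences of the element residual, with a
  reduced (degree-3) rule — the tangent only shapes the iteration path,
  never the converged solution, whose residual always uses the full rule.
  The factorised Jacobian is reused across iterations and refreshed when
  progress stalls. Cavity pressure is a follower load
  ($t = -p\,J F^{-T}N$) on the `ENDO` surface; on Newton failure the
  pressure increment is bisected (load stepping).
* **Fluid solve.** Backward Euler in time. Within a coupled step the
  fluid unknowns are the nodal $m_i$; the pointwise nonlinear map
  $m \mapsto p$ uses nodal kinematic scalars ($J$, $\bar I_1$,
  $\bar I_2$) obtained by volume-weighted projection of element-centroid
  values, and is solved by Newton with the analytic pointwise tangent
  $\partial p_i/\partial m_k = a e^W (G_i G_k + 2 D_3 Q_3^i
  Q_3^k)/\rho_f$.
* **Coupling.** Partitioned fixed point per time step: solid solve with
  $m$ frozen, then implicit fluid update with the deformation and
  $\lambda$ frozen, until the maximum relative increments of $y$ and $m$
  fall below `tol_fixed_point` (default 1e-6). Flux vectors are recovered
  only after convergence.
* **Constraint residual.** A mixed P2/P1 method enforces the volume
  constraint weakly; the reported residual is its discrete (P1-weighted
  nodal) form, $\max_b |\int (J - 1 - \sum_i m_i/\rho_f) N_b\,dV| /
  \int N_b\,dV$, which the solver drives below tolerance. A pointwise sup
  over quadrature points would instead measure the $O(h)$ interpolation
  gap between the quadratic $J$ and the linear $m$ fields, which no
  consistent finite-element scheme controls.
* **Source time integration.** Prescribed source ramps enter each
  backward-Euler step through their step-averaged value, which integrates
  a linear ramp exactly; all other terms are implicit Euler. This keeps
  the delivered fluid mass equal to the protocol's target independent of
  the step count.

## The synthetic vascular generator

Imaged coronary trees are not redistributable, so `generate_synthetic_tree()`
emulates their structural features with a seeded recursive bifurcation
scheme: Murray-law radii ($r_p^\gamma = \sum r_c^\gamma$, $\gamma = 3$),
segment length proportional to radius, several disjoint subtrees feeding
distinct territories, a configurable mean flow split (`split_mean`) whose
asymmetric setting produces the dominant trunks that traverse real
perfusion territories shedding smaller branches, optimality-style
branching angles (the larger child deviates less), and occasional direct
small side vessels (`twig_prob`) reproducing the cross-scale connections
between non-neighbouring calibres seen in vascular morphology — the very
feature that motivates non-hierarchical compartment coupling. It does
*not* reproduce real anatomy: no curvature, no flow-adapted remodelling,
no venous return tree, and desk-scale segment counts (hundreds, against
millions in vivo). Conclusions from the comparison experiment are
therefore statements about the homogenisation pipeline's consistency, not
about any particular heart.

## The two experiments

### Discrete versus continuum (`run_network_comparison()`)

A seeded tree (one territory) is grown through a box of tissue sized to
hug the network; Poiseuille flow is solved with an arterial reservoir
(10 kPa) at the root and a venous-side reservoir at every terminal; the
homogenised three-compartment static Darcy model is driven by the *same*
two reservoir pressures, coupled in through the remaining half of the
root segment (arterial, into compartment 1) and half of each terminal
corridor (venous, out of compartment 3). Both solutions are volume
averaged on five axial slabs, weighted by the same local vessel fluid
volumes, so the continuum field is sampled where vessels exist. The
report's `max_rel_err` is the maximum over slabs of the absolute
discrete–continuum difference divided by the largest discrete slab
pressure. The terminal reservoir default (3 kPa) is the capillary-bed
pressure standing in for the vasculature below the generator's 0.14 mm
radius cut-off; setting it to venous zero would wrongly place the entire
downstream pressure drop inside the resolved terminals. The same
configuration, with `make_hierarchical()`, demonstrates the pressure
over-estimation of strictly hierarchical coupling; it is strict whenever
the tree contains a direct 1–3 connection.

### Passive inflation and wall stiffening (`run_passive_inflation()`)

An idealised wall (coarse thick-walled annulus by default; a truncated
ellipsoid shell is available) with base plane fixed and a diastolic
cavity pressure ramp, 0 to 1.5 kPa over 1 s in 6 steps, solved once
unperfused and once perfused: a spatially uniform source into compartment
1 ramps linearly so that its integrated mass equals 8 % of the reference
wall volume times the fluid density. Material parameters, permeabilities
(0.1 mm² kPa⁻¹ s⁻¹ isotropic) and the adjacent-compartment exchange
(1e-4 g mm⁻³ kPa⁻¹ s⁻¹) are spatially uniform to isolate the garden-hose
mechanism from parameterisation detail. Outputs: cavity volume (by a
divergence-theorem integral over the deformed quadratic endocardial
surface, closed by fanning boundary loops to their centroids), wall
volume $\int J\,dV$, total fluid mass, constraint residual, and
instantaneous compliance $dV/dp$ by central differences (one-sided at the
ends). The perfused wall reaches the 8 % volume increase by construction
of the constraint plus mass balance — which is exactly why it is a sharp
end-to-end test of the partitioned solver — and ends with a smaller
cavity volume than the unperfused wall: perfusion stiffens the ventricle.
At the lowest pressures the perfused compliance can transiently exceed
the unperfused one, the fluid-induced deformation outweighing the
stiffening before the exponential law takes over.

### Problem sizes

The default experiments are desk-scale: the annulus wall has 240
tetrahedra (about 500 quadratic displacement nodes), runs in a few
minutes on one core, and the comparison uses a ~600-segment tree on a
128-element box in seconds. All sizes are configurable; the defaults were
chosen as the coarsest discretisations whose qualitative behaviour was
stable under one uniform refinement.

## Known limitations

* Isotropic skeleton: no fibre architecture, so perfusion-induced strain
  distributes differently than in fibre-reinforced tissue; no active
  contraction.
* Per-region constant $K$, $\phi$, $\beta$: sub-regional heterogeneity is
  smeared; the comparison experiment quantifies the cost.
* The $\beta$ estimator is topological; it tracks the flow-derived
  transfer coefficient within a factor of ~2 on trees of this family, not
  exactly.
* Newtonian blood, rigid vessel walls within a compartment, no gravity or
  inertial corrections, quasi-static solid.
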