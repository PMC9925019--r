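---
title: "Methods: GLS-stabilized power-law MHD flow in a stenosed bifurcated artery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GLS-stabilized power-law MHD flow in a stenosed bifurcated artery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Model

`stenofem` solves the steady, two-dimensional, incompressible momentum
and mass balance of a generalized Newtonian liquid subject to a
transverse magnetic field. In dimensionless variables (lengths scaled by
the inlet height $\bar h = 2a$, velocities by the mean inflow velocity
$\bar u_r$, pressure by $\rho \bar u_r^2$):

$$
\nabla\cdot\mathbf u = 0,\qquad
\mathbf u\cdot\nabla\mathbf u
  = -\nabla p + \frac{1}{Re}\,\nabla\cdot\bigl(2\eta(\dot\gamma)\mathbf D\bigr)
    - \frac{M^2}{Re}\,u\,\mathbf e_x ,
$$

with the strain-rate tensor $\mathbf D = (\nabla\mathbf u +
\nabla\mathbf u^T)/2$ and the power-law apparent viscosity
$\eta = |I_2|^{(n-1)/2}$, where $I_2 = 2u_x^2 + 2v_y^2 + (u_y+v_x)^2$
is the second strain-rate invariant. The Lorentz body force acts only
on the axial velocity component (the applied field is transverse and
the induced field is neglected — the low magnetic Reynolds number
approximation). The dimensionless groups generalize the classical ones
to a power-law consistency $m$:

$$
Re = \frac{\rho \bar h^{\,n} \bar u_r^{\,2-n}}{m},\qquad
M = B_0\sqrt{\frac{\sigma \bar h^{\,n+1}}{m\,\bar u_r^{\,n-1}}}.
$$

Assumptions: laminar, steady, fully developed inflow; rigid walls; no
heat transfer; single-phase continuum blood (no cell suspension). The
viscosity function is printed in some sources with a negative sign; a
negative viscosity is unphysical, and the positive form is used.

### Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `a` | m | 0.0075 | mother-artery radius; $\bar h = 2a$ |
| `tau_m` | m | 0.4 a | stenosis depth (40 % occlusion) |
| `l0`, `d` | m | 0.015, 0.005 | stenosis length and onset |
| `beta` | rad | $\pi/6$ | branch half-angle |
| `q` | m | 2e-4 | junction compatibility offset (range 1e-4 to 5e-4) |
| `n` | — | 1 | power-law index (0.639 shear-thinning, 1.2 shear-thickening) |
| `Re`, `M` | — | 300, 0–12 | Reynolds and Hartmann numbers |
| `gamma_floor` | — | 1e-6 | shear-rate regularization floor |

For $n<1$ the power law diverges as $\dot\gamma\to 0$; the floor caps
$\eta$ at $\eta_{\max} = \texttt{gamma\_floor}^{\,n-1}$ (about 147 at
$n = 0.639$). The floor only activates in stagnant pockets; solutions
are insensitive to it over one to two decades because the momentum
balance there is dominated by the pressure gradient. It is configurable
through `solve_flow(gamma_floor = )`.

The inlet profile is $u(y) = \tfrac32\bigl(1 - (|y|/0.5)^{(n+1)/n}\bigr)$,
taken verbatim for all $n$. The $3/2$ prefactor normalizes the *mean*
inflow to 1 only at $n = 1$; for other indices the profile is the
fully developed power-law shape with unit-normalized centreline scaling
(mean 1.079 at $n = 0.639$, 0.971 at $n = 1.2$). We keep the printed
form rather than re-normalizing the flux, and report means per case.

## Geometry

The bifurcated domain is defined by two closed-form wall radii: the
outer wall (constant radius, a quartic two-throat "overlapping"
stenosis profile $a - \tfrac32\tau_m(11t - 47t^2 + 72t^3 - 36t^4)$ with
$t = (x-d)/l_0$, a circular lateral-junction arc, then a straight
diverging branch wall) and the inner wall (zero up to the flow-divider
apex, a circular divider arc, then a straight inner branch wall). The
quartic attains its minimum $a-\tau_m$ exactly at $d + l_0/3$ and
$d + 2l_0/3$ and a local interior maximum $a - \tfrac34\tau_m$ at
mid-stenosis; the geometry tests assert these to 1e-12. Only the upper
half is given in closed form; the computational domain is the
mirror-symmetric closure about the channel axis, consistent with the
two printed outlet pressure-pin points, one per branch. Each daughter
outlet is closed by the straight segment joining the outer-wall
endpoint $(x_{max}-s,\pm R_1)$ to the inner-wall endpoint
$(x_{max},\pm R_2)$; that segment is perpendicular to the branch axis,
so no additional rotation of the outlet face is applied. Under the
default parameters the dimensionless outlet corners evaluate to
$(4, 1.1556)$ and $(3.745, -1.5973)$, matching the printed pin
coordinates to the 4 printed digits (the 5th digit of the first pin
rounds from 1.15560).

The straight-channel builder (`straight_channel_domain`) provides the
verification domain: a rectangle with an optional user-supplied
symmetric constriction (`cosine_bump` is the documented default). The
bell-shaped constriction used in some published validation studies is
not available in closed form here, so the builder accepts any profile
instead of hard-coding one.

## Meshing

No unstructured Delaunay-refinement engine is available in this R
stack, so `generate_mesh` implements a mapped column-wise
triangulation designed for exactly this family of domains: nodes are
laid on vertical stations that follow the parametric walls; strips
between stations are triangulated row by row, with the quad diagonal
chosen as the shorter one and ties broken by the side of the axis
(which makes meshes of mirror-symmetric domains exactly mirror
symmetric — wall traces on the two outer walls agree to machine
precision); the tapering outlet wedges use a two-pointer
shortest-diagonal sweep that tolerates unequal node counts and
geometric station grading toward the tip. Axial spacing is
`global_max` (default 0.03) away from the stenosis and
`global_max * stenosis_factor` (default 0.6) over the stenotic zone
plus one stenosis length downstream, with extra grading over the first
and last 12 % of the stenosis where the quartic wall is steepest.

The defaults produce 12 686 elements on 6 638 nodes for the study
geometry — inside the 11 000–13 000 / 6 000–8 000 band established by
the mesh-independence ladder for this domain family. Limitations: the
element size measure `h_K` is the longest edge (the quantity the
stabilization parameter uses; circumdiameter or $\sqrt{2\,\text{area}}$
could be substituted in `element_metrics`), strip diagonals reach about
1.4x `global_max`, and a handful of elements at the steep stenosis ends
sit at interior angles of 17.6–20 degrees; everything else respects a
20-degree minimum. Mesh reproducibility is pinned by recording the
boundary polyline and the sizing parameters, not the mesh itself.

## GLS discretization

Velocity and pressure are both continuous piecewise-linear (P1/P1) on
triangles. The classical Galerkin form is augmented elementwise with
the least-squares term

$$
\sum_K \int_{\Omega_K} \bigl(\mathbf u\cdot\nabla\mathbf u + \nabla p
 - \mathbf f\bigr)\cdot \tau(Re_K)\,
 \bigl(\mathbf u\cdot\nabla\mathbf N - \nabla q\bigr)\,d\Omega ,
$$

where the viscous part of both operators vanishes for linear elements.
The stabilization parameter is

$$
\tau(Re_K) = \frac{h_K}{2|\mathbf u|_p}\,\xi(Re_K),\quad
Re_K = \frac{m_K |\mathbf u|_p h_K\,Re}{4\eta},\quad
\xi = \min(Re_K, 1),\quad m_K = \tfrac13 .
$$

Two transcription choices are deliberate. First, the printed element
Reynolds number carries a dimensional density prefactor; in the
dimensionless system the consistent reading replaces $\rho/\bar\eta$ by
$Re/\eta$, which is the default (`tau_form = "dimensionless"`; the
literal dimensional reading is switchable and differs only by the
factor $Re$). Second, in the diffusive branch $Re_K < 1$ the
algebraically equivalent form $\tau = m_K h_K^2 Re/(8\eta)$ is used,
which is finite as $|\mathbf u|_p \to 0$. The velocity norm and $\eta$
entering $\tau$ are sampled at the element centroid from the current
iterate (per-quadrature-point sampling is the obvious alternative; the
centroid choice keeps $\tau$ elementwise constant, which the
translation-invariance and symmetry tests rely on).

Integrals use the six-point, degree-4 Gaussian rule on triangles. For
P1 elements every integrand in the residual is polynomial of total
degree at most 2, so this rule is exact; it is asserted against the
closed-form monomial moments in the tests.

Boundary conditions: Dirichlet velocity on walls (no slip) and on the
inflow (the profile above), traction-free natural outflow on the two
outlet faces, and two pressure pins $p = 0$ at the outlet/wall corner
nodes, snapped to the nearest boundary node within one element size.
Dirichlet rows are imposed by row replacement (identity row, prescribed
value), not penalty, so the residual retains its interpretation in the
stopping rule.

## Newton solver

The residual is assembled in vectorized form over all elements; the
analytic Jacobian differentiates every term, including
$\partial\eta/\partial\nabla\mathbf u = \tfrac{n-1}{2}\,\eta/I_2\,
\partial I_2/\partial\nabla\mathbf u$ (regularized to zero where the
floor is active). $\tau$ is refreshed every iteration but held constant
under differentiation; the finite-difference oracle in the tests
perturbs the residual with $\tau$ frozen at the base iterate, and the
analytic Jacobian matches it to 1e-9 relative on small meshes. A
frozen-viscosity (Picard-like) Jacobian that omits the $\eta$
derivatives is available as a fallback; the solver tries one such step
automatically when the analytic step stalls.

The iteration is $U^{b+1} = U^b - J^{-1}R(U^b)$ with automatic step
halving while the residual sum of squares grows, and a divergence error
after three consecutive non-improving damped steps. Linear systems are
solved by sparse LU (`Matrix`).

**Stopping rule.** A case is declared converged when
$\sum_I R_I^2 \le 10^{-4}$. That threshold alone, however, is loose on
these meshes: residual entries scale like $h^2$ times the local force
balance, so states whose velocity field still differs by several
percent from the discrete root all satisfy it (the Hartmann-channel
test makes this concrete). Newton therefore keeps iterating after the
declaration until the residual stagnates or reaches
`tol_stop = 1e-12` — typically one or two extra iterations, thanks to
quadratic convergence — so post-processed quantities do not depend on
where inside the loose convergence basin the iteration stopped.

**Continuation.** The initial iterate is the linear Stokes solution
(advection dropped, $n = 1$, the linear Lorentz term retained). The
default schedule then solves Newtonian Navier-Stokes at the target
$Re$, then the target $n$, then ramps $M$ in steps of at most 4. A
ladder request (`M_values = c(0, 4, 8, 12)`) reuses each converged
state to seed the next stage and returns all requested solutions; the
tests verify that staged and direct continuation land on the same
state. The pipeline contains no randomness; reruns are bit-identical
on the same mesh.

## Post-processing

* **Wall shear stress** $\tau_w = m\,\eta\,(u_y + v_x)$ on the
  wall-adjacent element of each boundary edge (P1 gradients are
  elementwise constant), averaged between adjacent edges at shared
  nodes; $m = 1$ by default for dimensionless output.
* **Cross-sections** are vertical chords $x = \text{const}$ (matching
  the "at x = ..." convention, including inside the inclined daughter
  branch, where the axial component $u$ is reported; the branch-aligned
  component is computable from $(u, v, \beta)$). Means are trapezoidal.
* **Recirculation.** The flow-reversal measure is the area of
  $\{u < 0\}$, computed exactly per element by clipping the linear
  field, over elements whose centroid lies downstream of the stenosis
  offset ($x > d + l_0$, no upper bound — the pockets extend through
  the junction into the daughter branches). This is an *operational*
  definition: published percentage reductions rarely state theirs, and
  the number is sensitive to the window (restricting it to the junction
  region alone changes both the magnitudes and the ordering across
  rheologies), which is why `recirculation_area` exposes the window as
  arguments and the acceptance machinery reports the values under the
  documented default.
* **Streamfunction** by a P1 Poisson solve of $-\Delta\psi = \omega$
  with boundary values accumulated from the normal flux along the
  (counter-clockwise) boundary loop; closed $\psi$ contours mark the
  recirculation pockets in plots.
* **Mass audit:** inflow/outlet fluxes are line integrals of
  $\mathbf u\cdot\mathbf n$ with outward normals determined from the
  adjacent element; GLS is not elementwise conservative, and the net
  imbalance below 1 % of the inflow flux on the study meshes is the
  acceptance contract. This also bounds what chord-mean velocities can
  resolve: the mean axial velocity over a full cross-section is fixed
  by the (conserved) flux, so its variation with $M$ is of the order of
  the conservation error, not of the visible profile changes.

## What the parametric domain does and does not emulate

The geometry generator reproduces an idealized 2-D bifurcation: exact
mirror symmetry, rigid walls, a single analytic stenosis, straight
daughter branches at a fixed half-angle. Real arteries are
three-dimensional, compliant, asymmetric, and pulsatile; passing the
suite therefore demonstrates the correctness of the discretization and
solver on the stated model, not predictive accuracy for patient
anatomy. Within the model, the verification ladder (power-law
Poiseuille and Hartmann closed forms, finite-difference Jacobians,
mesh-refinement convergence) checks every ingredient that the
bifurcated runs rely on.

## Known limitations

* P1/P1 only; the quadratic pair (with $C_K = 1/48$ in $m_K$) is
  documented in the stabilization constant but not implemented.
* Steady flow only; no pulsatile indices (OSI etc.).
* The wedge tips at the outlet corners concentrate a few thin
  elements; pressure pins sit exactly there, which regularizes the
  corner but makes the last centimetre of the wall-pressure trace
  mesh-sensitive.
* The Hartmann body force uses the axial-velocity-only form; at large
  $M$ with strongly two-dimensional flow a full $\mathbf J \times
  \mathbf B$ coupling would differ.
* Problem sizes used by the test-suite and the acceptance script: the
  default study mesh (~12.7k elements) for the bifurcated runs and
  2.5k-11k-element channels for the oracles; these sit inside the
  mesh-independence band established for this domain family.
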