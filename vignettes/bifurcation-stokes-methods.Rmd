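---
title: "Stokes flow in a 2D bifurcation: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stokes flow in a 2D bifurcation: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical problem

Microvascular and microfluidic networks are usually modelled as graphs of
channel segments, each carrying a conductance: the flux per unit pressure
drop.  For a straight two-dimensional channel of width $D$ and length $L$
(in units of the parent channel width, with viscosity scaled out), plane
Poiseuille flow gives $\tilde G = D^3/(12 L)$.  At a junction this idealised
law ignores everything about the junction geometry.  This package solves the
full Stokes problem in a single bifurcation — one parent channel and two
child channels of widths $D_1$, $D_2$ leaving the junction at angles
$\alpha$ (upper) and $\beta$ (lower), each of centreline length $L$ — and
reduces the solution to the network quantities, so that the error of the
Poiseuille approximation can be quantified and replaced.

The flow is inertialess, incompressible and Newtonian:
$\nabla^2 \mathbf u = \nabla p$, $\nabla\cdot\mathbf u = 0$ in dimensionless
variables (lengths by the parent width $d$, velocities by $q/d$ with inlet
flux $q$, pressures by $\mu q/d^2$; the `dimensional_scales()` helper is the
only place dimensional quantities appear).  Boundary conditions are zero
velocity on the walls, and at each of the three openings a prescribed
pressure together with parallel flow — equivalent to fully developed
parabolic inflow/outflow.  The inlet pressure is grounded at $P_0 = 0$.

## Goursat representation and rational approximation

In complex form $\zeta = X + iY$, any biharmonic stream function can be
written $\psi = \mathrm{Im}[\bar\zeta f(\zeta) + g(\zeta)]$ with $f$, $g$
analytic (the Goursat pair).  Velocity, pressure and vorticity follow as

$$U - iV = -\overline{f(\zeta)} + \bar\zeta f'(\zeta) + g'(\zeta),
\qquad P - i\Omega = 4 f'(\zeta).$$

Both Goursat functions are approximated by the same rational basis:

* an **Arnoldi-orthogonalised polynomial** of degree $n$ (the
  Vandermonde-with-Arnoldi recurrence built on the boundary samples; its
  derivative is obtained by differentiating the recurrence, never by finite
  differences),
* **lightning poles** at each reentrant corner: $N$ simple poles at
  distances $\ell\,e^{-\sigma(\sqrt N - \sqrt k)}$, $k = 1..N$, along the
  into-solid bisector, the clustering that yields root-exponential
  convergence for corner singularities,
* for curved (Bezier) walls, poles obtained by running the **AAA algorithm**
  on the Schwarz function $F(\zeta) = \bar\zeta$ of each arc and keeping the
  poles outside the fluid,
* for an embedded circular particle, a **Laurent block**
  $(\zeta-\zeta_0)^{-j}$, $j = 1..q$, about the particle centre in both $f$
  and $g$, plus the three single-valued logarithmic degrees of freedom of a
  hole: a stokeslet pair ($a\log w$ in $f$ coupled with
  $-\bar a\,(w\log w - w) - \bar\zeta_0 a \log w$ in $g$, $w=\zeta-\zeta_0$)
  carrying the net force, and a rotlet ($i t \log w$ in $g$, $t$ real)
  carrying the net torque.  The coupling is built into the basis columns, so
  every basis function has single-valued velocity *and* stream function and
  the branch of the logarithm is immaterial.  Omitting the rotlet is not a
  small effect: an asymmetrically forced particle carries nonzero torque,
  and without that column the boundary residual stalls near $10^{-3}$.

Pole and Laurent columns are scaled to unit maximum modulus on the
boundary.  Each complex coefficient contributes its real and imaginary part
as separate real unknowns, so the collocated boundary conditions form a real
least-squares problem: two rows (both velocity components) per wall or
particle sample, and two rows (pressure via $\mathrm{Re}\,4f'$, zero
transverse velocity) per opening sample, every row weighted by the square
root of the sample's arc-length weight.  An alternative full normal-stress
opening condition is available (`normal_stress = TRUE`); for parallel flow
the two coincide, which the test suite verifies on a straight channel.

### Collocation sampling

Wall samples interleave `wall_oversample` (default 4) points per pole over
the same root-exponential depth range as the pole cluster, plus a uniform
complement; openings use Chebyshev-type clustering toward their ends.
Matching the sample depth to the pole depth matters: sampling far below the
innermost pole adds rows the basis cannot satisfy, and letting poles reach
below it (e.g. 96 poles per corner at $\sigma = 4$) destabilises the solve.
Defaults (polynomial degree 24, 48 poles per corner for straight walls;
degree 48 with AAA poles for curved walls; degree 80 with a degree-20
Laurent block for the particle case) reproduce the accuracy figures quoted
below.

Two further choices are worth recording.  First, the wall/opening junctions
of the truncated channels carry weak convex-corner singularities induced by
the artificial opening conditions; small pole clusters
(`opening_corner_poles`, default 16) behind those six corners remove a
residual floor near $10^{-8}$.  Second, the truncated-SVD threshold for the
rank-deficient least-squares problem (the Goursat gauge freedom makes a few
directions null) is $10^{-14}\,\sigma_{\max}$: looser truncation ($10^{-12}$)
measurably raises the boundary error floor, tighter makes no further
difference.

### Accuracy measurement

`boundary_residual()` reports the maximum boundary-condition violation on a
uniform arc-length grid refined relative to the solve sampling — the measure
under which the solver reaches below $10^{-8}$ on the reference geometry at
the default basis — and separately a `near_corner` figure measured on a
corner-clustered grid that reaches the innermost pole distance
($\approx 5\times10^{-11}$ at 48 poles).  Within $\sim10^{-3}$ of a
reentrant corner the absolute velocity error grows to $\sim10^{-7}$: the
velocity itself decays like $r^{0.54}$ there, and no double-precision
rational basis resolves the power singularity below its innermost pole.
Both numbers are reported; neither is hidden in the other.

## Network reduction

Solving twice with outlet pressures $(1,0)$ and $(0,1)$ yields the
$2\times2$ tensor mapping outlet pressures to outlet fluxes (columns are
measured fluxes; fluxes are computed as stream-function differences across
each opening and cross-checked by 64-point Gauss quadrature of
$\mathbf u \cdot \mathbf n$).  The conductance triple $(G_0, G_1, G_2)$ of
the equivalent star network follows in closed form from the two solves; the
implementation asserts that rebuilding the tensor from the triple matches
the measured tensor to $10^{-4}$ relative (failure indicates an unconverged
solve), and falls back to a direct tensor-based inversion when the
closed-form denominators cancel (exactly symmetric geometries).  Tensor
reciprocity $G_{12} = G_{21}$ is not imposed anywhere, which makes it a
sharp end-to-end solver check.

Two reference conductance sets are provided: the Poiseuille triple
$\tilde G_i = D_i^3/(12L)$ with its network tensor, and the area-preserved
triple $\hat G_i = \hat D_i^3/(12L)$ with effective widths
$\hat D_i = A_i/L$, where the region areas $A_i$ split the fluid domain by
connecting the origin to the three wall corners (straight walls) or to the
Bezier midpoints $t = 0.5$ (curved walls), subtracting any clipped particle
overlap (Sutherland-Hodgman clipping of a 720-gon circle).

## Flow partition and separatrices

Because the problem is linear, the flow for any $(P_1, P_2)$ is a
superposition of the two cached base solutions; `constrained_flow()` uses
this to realise a prescribed $\Delta P = P_1 - P_2$ at unit inlet flux
without further solves.  The reversal threshold — the $\Delta P$ at which
child channel 1 stalls — follows in closed form from the tensor and is
verified by a sign-change bracket.  The separating streamline is anchored in
flux coordinates: for forward flow its inlet ordinate $Y^*$ satisfies
$\int_{-1/2}^{Y^*} U\,dY = Q_2$, which is robust where shooting from the
corner is ill-conditioned; for reversed child-1 flow the level equals the
upper-parent-wall stream function and the streamline is found where it
crosses opening 2, then traced upstream.  Streamlines are integrated with an
embedded Fehlberg 4(5) pair on the unit-speed field, tolerance $10^{-9}$ per
step; the stream-function drift along traced paths stays below $10^{-6}$
(typically $10^{-9}$ or better).

## Surrogate models

`generate_dataset()` rejection-samples geometries uniformly
($D_1, D_2 \in [0.5, 1]$, $\alpha, \beta \in [0, \pi/2]$ for straight or
curved walls; particle centre in $[-1,1]^2$ with radius in $(0, 0.3]$ for
the particle space), discards invalid geometries via `validate_spec()` and
solves each accepted row.  The angle predicate extends the sweep exclusion
$\alpha + \beta \ge \pi/2$ to all widths: the solid wedge between the child
channels thins out regardless of the widths, and the excluded corner of the
angle square is equally degenerate at $D_i < 1$.  Bulk solves use a reduced
basis (`sweep_options()`: degree 16, 24 poles per corner) whose conductances
agree with the full basis to about $10^{-6}$ relative — three orders below
the surrogate's own error — at roughly half a second per geometry; rows
whose collocation residual exceeds $10^{-4}$ are re-solved at doubled
resolution and flagged if still above.

The regressor is a fixed $[\,d_{\mathrm{in}}, 20, 20, 20, 1\,]$ feedforward
network with rectified-linear activations, one independent model per
conductance component, trained full-batch by L-BFGS on z-scored inputs (the
target is internally scaled to unit variance for optimiser conditioning;
all reported errors are on the raw conductance scale), no regularisation,
up to 5000 iterations.  With 1000 straight-geometry samples and an 80/20
split, validation MSE reaches the $10^{-7}$–$10^{-6}$ decade; the exact
value is seed-dependent.  The test suite runs a 200-sample version and
asserts MSE $< 10^{-5}$ together with the structural checks (determinism,
swap symmetry, improvement over the Poiseuille map).  Since weight
initialisation and L-BFGS are deterministic given the seed, results are
bit-reproducible on one platform.

## What the synthetic spaces do and do not emulate

The generated geometries are ideal single bifurcations: straight or
single-Bezier walls, rigid boundaries, one rigid circular particle at most,
Newtonian fluid, zero Reynolds number.  Passing tests demonstrate the
solver and reduction on exactly this class.  They say nothing about
red-blood-cell rheology, deformable or multiple particles, finite inertia,
three-dimensional effects, or junctions of more than three channels — all
outside the package's scope.  The Bezier wall construction places both
interior control points at the straight-geometry corner scaled by
`bezier_control_fraction` (default 1) along each wall, guaranteeing
tangency to the straight walls at the openings so the parabolic opening
conditions remain consistent; other curved-wall families would need their
own control-point rule, and quantitative curved-wall results depend on this
choice.

## Degenerate inputs and tie-breaks

Angles of exactly $0$ or $\pi/2$ are supported; a child collinear with the
parent ($\beta = 0$, $D_2 = 1$) makes one wall a straight corner-free
segment, which simply receives no pole cluster.  Corner bisectors come from
the two adjacent wall tangents.  A particle must clear the walls by at
least $10^{-3}$.  `validate_spec()` never throws — it returns the violated
predicates — while `build_bifurcation()` refuses invalid specs with the
same messages.

## Problem sizes used in the checks

Single solves use the full defaults (about 1000–2500 real unknowns,
seconds each).  The width-grid study runs a $6\times6$ grid and the
surrogate check 200 geometries at the reduced sweep basis; these sizes keep
the whole suite in the tens of minutes on one core while leaving every
qualitative and quantitative assertion at its stated tolerance.

## A worked call

```{r example}
library(bifstokes)

spec <- bif_spec(0.9, 0.8, pi / 4, pi / 3, L = 2)
dom <- build_bifurcation(spec)
cs <- conductance_tensor(dom)
tidy(cs, reference = poiseuille_reference(spec))

th <- reversal_threshold(conductance_tensor(
  build_bifurcation(bif_spec(1, 1, pi / 4, pi / 4))))
c(stokes = th$stokes, poiseuille = th$poiseuille)
```
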