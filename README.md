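# bifstokes

Stokes flow and flow conductance of two-dimensional channel bifurcations.

Flow networks — microvascular beds, microfluidic chips — are usually reduced
to graphs whose edges carry a conductance, the flux per unit pressure drop.
For a straight 2D channel of width `D` and length `L` (dimensionless, with
the parent width and viscosity scaled out), plane Poiseuille flow gives
`G~ = D^3 / (12 L)`.  At a junction this idealised law ignores the junction
geometry entirely.  `bifstokes` solves the full Stokes problem in a single
bifurcation — a parent channel splitting into two children of widths `D1`,
`D2` at angles `alpha`, `beta`, each of centreline length `L` — and reduces
it to the network quantities, so the junction can be represented accurately
in a network model.

The solver writes the stream function in the Goursat form
`psi = Im[conj(z) f(z) + g(z)]` with analytic `f`, `g`, and approximates both
by rational functions: an Arnoldi-orthogonalised (Vandermonde-with-Arnoldi)
polynomial, poles exponentially clustered at the reentrant corners
("lightning" poles), AAA-derived poles from the Schwarz function of curved
(Bezier) walls, and, for an embedded circular particle, a Laurent block plus
single-valued stokeslet/rotlet log terms.  Velocity, pressure and vorticity
follow from `U - iV = -conj(f) + conj(z) f' + g'` and `P - i Omega = 4 f'`;
boundary conditions are collocated into a weighted real least-squares
problem.  On top of the solver the package computes:

* the 2x2 conductance tensor and the triple `(G0, G1, G2)` of the
  equivalent three-edge star, from two solves with pressure vectors `(1,0)`
  and `(0,1)`,
* Poiseuille and area-preserved reference conductances and relative
  differences,
* flow partition under a fixed inlet flux, reverse-flow thresholds, centre
  and separating streamlines,
* neural-network surrogates (three `[in, 20, 20, 20, 1]` rectified-linear
  regressors) of the conductance components over geometry parameter spaces.

## A worked example

```r
library(bifstokes)

spec <- bif_spec(D1 = 0.9, D2 = 0.8, alpha = pi / 4, beta = pi / 3, L = 2)
cs <- conductance_tensor(build_bifurcation(spec))
tidy(cs, reference = poiseuille_reference(spec))
#> # A tibble: 3 x 4
#>   channel      G  G_ref rel_pct
#>   <chr>    <dbl>  <dbl>   <dbl>
#> 1 parent  0.0422 0.0417    1.34
#> 2 child1  0.0313 0.0304    2.93
#> 3 child2  0.0226 0.0213    5.73
```

The computed parent conductance `G0 = 0.0422` exceeds its Poiseuille
estimate `1/(12 L) = 0.0417` by 1.34%: the junction passes slightly more
flow than three idealised straight channels would, and the narrower child 2
deviates most (5.73%).  Flow-partition analysis on the symmetric bifurcation
(`D1 = D2 = 1`, `alpha = beta = pi/4`):

```r
sym <- conductance_tensor(build_bifurcation(bif_spec(1, 1, pi / 4, pi / 4)))
th <- reversal_threshold(sym)
c(stokes = th$stokes, poiseuille = th$poiseuille)
#>     stokes poiseuille 
#>   22.49262   24.00000
```

Under unit inlet flux, flow in child channel 1 reverses once the outlet
pressure difference `P1 - P2` exceeds 22.49; the idealised network model
predicts 24.  With a fixed cylinder of radius 0.2 at the junction centre the
threshold rises to 33.23.

A thin command-line wrapper (`inst/cli/bifstokes.R`) exposes the same
functionality as `solve | conduct | sweep | threshold | separatrix |
surrogate` subcommands over JSON configurations, writing CSV/JSON results
with a provenance sidecar.

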