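---
title: "Models and methods: resource limitation and the realized thermal niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: resource limitation and the realized thermal niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoniche)
```

## The model and its assumptions

`thermoniche` studies a single consumer–resource pair in which every vital
rate responds to a constant environmental temperature $T$ (°C throughout;
no Kelvin conversion, since all parameters are calibrated on the Celsius
scale).

The consumer's per-capita growth is bioenergetic:

$$\frac{dC}{C\,dt} = (1-\delta)\,f(R,T) - m(T),$$

with three assumptions that jointly produce every qualitative result in the
package:

1. **Respiration rises (approximately) exponentially**,
   $m(T) = m_a e^{m_b T} + m_c$, a simple-exponential stand-in for
   Boltzmann–Arrhenius scaling that is accurate over the biologically
   relevant range and keeps all algebra closed-form.
2. **Maximum ingestion is symmetric unimodal**,
   $I_{max}(T) = e^{-(T-T_I)^2/\beta}$, peaking at the ingestion optimum
   $T_I$ with breadth $\beta$. Empirical ingestion curves are often
   left-skewed; the symmetric form changes none of the qualitative
   conclusions and is the deliberate choice here (asymmetric forms are out
   of scope).
3. **Only the functional response sees resource density**:
   $f(R,T) = I_{max}(T)\,R/(R+R_0)$, Michaelis–Menten with a
   temperature-invariant half-saturation density $R_0$ — justified because
   attack rate and inverse handling time respond similarly to temperature,
   so their ratio is roughly constant. The Holling equivalences
   $I_{max} \equiv 1/h$, $R_0 \equiv 1/(a h)$ are exposed by
   `holling_coefs()`.

Because ingestion is bounded by $I_{max} \le 1$ while respiration keeps
rising, the interplay reshapes the TPC as resources decline: `Tmin` rises,
`Tmax` falls, and the optimum shifts cooler. The whole geometry is carried
by the zero-net-growth isocline (ZNGI)

$$R^*(T) = \frac{R_0\, m(T)}{(1-\delta) I_{max}(T) - m(T)},$$

defined where $(1-\delta)I_{max}(T) > m(T)$. `niche_envelope()` assembles
$R^*(T)$, the ridge of optima $T_{opt}(R)$, and the collapse point
$\arg\min_T R^*(T)$ where the niche contracts to one temperature. The
boundary is *measured*, not assumed symmetric about the collapse point (it
is only approximately so).

Two resource closures complete the system:

- **Chemostat** (`chemostat_rhs()`): $dR/dt = D(S-R) - f(R,T)C$ with
  temperature-independent supply. Coexistence, where feasible with
  $\hat R = R^*(T) < S$, is provably stable (Jacobian trace
  $-D - I_{max}\hat C R_0/(\hat R+R_0)^2 < 0$, determinant $> 0$), so the
  only bifurcations are the two transcritical invasion boundaries where
  $(1-\delta)f(S,T) = m(T)$.
- **Logistic resource** (`logistic_rhs()`):
  $dR/dt = r(T)R(1 - R/K(T)) - f(R,T)C$ with
  $r(T) = b_{max} e^{-(T-T_I-\Delta T)^2/\beta_r} - (d_0 + d_1 e^{d_2 T})$
  and $K(T) = r(T)/\gamma$. Tying $K$ to $r$ through a
  temperature-independent density-dependence strength $\gamma$ enforces the
  sign constraint — $r$ and $K$ share zeros and sign — so density dependence
  keeps *opposing* growth when $r < 0$ instead of spuriously rescuing a
  declining population. The mismatch $\Delta T$ shifts the resource's
  thermal optimum relative to the consumer's $T_I$; $T_I$ itself is threaded
  into the resource functions from the paired `consumer_params` so
  `resource_traits` stays self-contained.

## Parameters

| parameter | meaning | units | default | why |
|---|---|---|---|---|
| $\delta$ | assimilation loss | – | 0.5 | mid-range conversion inefficiency |
| $m_a, m_b, m_c$ | respiration scale/exponent/offset | $t^{-1}$, °C$^{-1}$, $t^{-1}$ | 0.01, 0.1, 0.05 | standard worked-example consumer (numeric values as printed in the source material; their assignment to the individual symbols is inferred from the order of the rate definitions) |
| $T_I$ | ingestion optimum | °C | 25 | as above |
| $\beta$ | ingestion breadth | °C² | 150 | as above |
| $R_0$ | half-saturation density | resource | 0.5 | "efficient" consumer; 1 and 2 are the prudent variants |
| $S, D$ | chemostat supply, flow | resource, $t^{-1}$ | 1, 1 | printed chemostat configuration |
| $b_{max}$ | resource birth scale | $t^{-1}$ | 1 | calibrated (below) |
| $\beta_r$ | resource growth breadth | °C² | 150 | defaults to the consumer's $\beta$; stored separately so breadth mismatch is expressible |
| $d_0, d_1, d_2$ | resource maintenance | $t^{-1}$, $t^{-1}$, °C$^{-1}$ | 0.05, 0.005, 0.1 | calibrated (below) |
| $\gamma$ | density dependence | (resource·$t$)$^{-1}$ | 0.5 | calibrated (below) |
| $\Delta T$ | thermal mismatch | °C | 0 | scenario variable |

### Calibration of the resource defaults

The logistic-resource parameter set used in the original branch diagrams is
not recoverable from the source material, so the package ships calibrated
stand-ins satisfying the two stated structural conditions: (i) the resource's
fundamental niche ($r > 0$ on 4.31–38.65 °C) strictly contains the
consumer's saturated niche (7.96–33.08 °C); and (ii) the coexistence
equilibrium cycles for the efficient consumer ($R_0 = 0.5$) but for
$R_0 = 1$ or $2$ no limit cycle exists anywhere — including across the full
mismatch range of the regime diagram. Condition (ii) pins $\gamma$: the
coexistence state destabilises exactly where
$K(T) > R_0\,\frac{(1-\delta)I_{max}(T)+m(T)}{(1-\delta)I_{max}(T)-m(T)}$
(the classical enrichment threshold $K = 2R^* + R_0$, obtained by setting
the Jacobian trace to zero and substituting $R^*$ — verified by hand before
implementation and used as the test oracle for the numerical Hopf
detector). At $\gamma = 0.45$ the $R_0 = 1$ consumer narrowly crosses this
threshold on $T \in (21.4, 24.3)$, violating (ii); $\gamma = 0.5$ satisfies
both conditions with margin and is the shipped default. The search is
reproducible with `calibrate_defaults()`, which also re-derives the
calibrated mismatch fixtures: $\Delta T = -22$ °C (the smallest shipped
magnitude at which the realized $T_{max}$ falls left of the ZNGI minimum —
metabolic meltdown; beyond about $-23$ °C coexistence disappears entirely)
and $\Delta T = +12$ °C (the mirrored cold-edge case). The printed
mismatch scenarios $\Delta T = +9$ and $-18$ °C are shipped verbatim
(`fig5a`, `fig5b`) for comparison; under the calibrated defaults the
$-18$ °C case sits just short of the meltdown condition, which is why a
stronger calibrated value exists.

## Realized niches, regimes, and meltdown

The **realized TPC** (`realized_tpc()`) is the consumer's invasion growth
at the resource-only equilibrium, $g(\max(K(T),0), T)$. This is the
quantity that determines the persistence boundaries in the regime diagram
(coexistence begins exactly where it turns positive); the alternative —
performance along the coexistence attractor — answers a different question
and is not used. Where $K \le 0$ the curve is pure respiration loss
$-m(T)$.

`regime_grid()` classifies each $(\Delta T, T)$ cell by the stable
attractor of the logistic model: `extinct` ($r \le 0$), `resource_only`
($K \le R^*$ or $R^*$ infeasible), `coexist_stable`, or `coexist_cycles`
(coexistence exists, trace $> 0$).

`meltdown_report()` locates the realized limits (roots of $K = R^*$) and
attributes each edge by the sign of the ZNGI slope there: the warm edge is
`consumer_physiology` when $R^{*\prime}(T_{max}) > 0$ (the consumer's own
physiology failing, resources rebounding as top-down control relaxes) and
`resource_thermal_traits` when $R^{*\prime}(T_{max}) < 0$ (the consumer
still improving, thwarted only by the resource's thermal collapse — the
meltdown configuration); the cold edge is the mirror image. This slope rule
is exactly equivalent to the meltdown criterion "$T_{max}$ left of
$\arg\min_T R^*$" and reproduces every qualitative claim about which side
limits the niche under positive and negative mismatch. A coincidence rule
(edge within a fixed tolerance of the saturated consumer-only root) was
considered and rejected: in the logistic model the realized edges *always*
involve finite $K(T)$, so they essentially never coincide with the
saturated roots and the rule would label every edge resource-limited.

## Numerical choices

- **Root finding.** All bifurcation and boundary temperatures come from a
  coarse bracketing scan (default step 0.05 °C) followed by Brent's method
  (`uniroot`), refined to $10^{-6}$ °C for branch-scan bifurcations and
  $10^{-10}$ °C where a test oracle demands $10^{-6}$ agreement. The scanned
  functions are smooth with at most two roots in the scanned windows, so
  bracketing at 0.05 °C cannot skip a root pair except within one step of a
  tangency (the calibrated fixtures are not near that degeneracy).
- **Saturated limits** use the analytic $R \to \infty$ growth limit
  $(1-\delta)I_{max} - m$, not a large finite density.
- **$T_{opt}$** is located by golden-section search (`optimize`) inside the
  thermal limits; in exactly flat degenerate cases the search's lower-end
  bias breaks ties toward cooler temperatures.
- **Logistic form.** The right-hand side is evaluated as
  $rR - \gamma R^2$, algebraically identical to $rR(1-R/K)$ wherever
  $K \ne 0$ but free of the removable singularity at $r = 0$ and correct
  (strictly negative) when $r < 0$.
- **Equilibria are closed-form**; Jacobians are analytic, and stability is
  the sign of the leading eigenvalue real part. Equilibrium residuals are
  at numerical zero ($<10^{-10}$) by construction and verified in tests.
- **Integration** (`simulate_dynamics()`) uses `deSolve::ode` with `lsoda`,
  `rtol = 1e-10`, `atol = 1e-12`; nonnegativity is enforced by clipping the
  state at zero (tolerance $10^{-12}$) before derivative evaluation and in
  the output. Integration failures raise typed errors with the solver
  state.
- **Cycle summaries** discard a transient of 2000 time units and measure
  extrema over a 500-unit window (defaults); convergence requires the
  extrema of the two half-windows to agree within 1% (or $10^{-6}$
  absolutely). The period estimate is the mean spacing of interior resource
  maxima. Near a Hopf point transients decay slowly; the defaults suffice
  at distances $\gtrsim 0.3$ °C from the bifurcation.
- **Degenerate inputs.** A consumer whose growth is positive over the whole
  scan grid (no boundary) or negative everywhere (no niche) makes
  `niche_envelope()` fail with a clear error rather than return an
  unbounded envelope; negative carrying capacities are never reported as
  equilibria, and a coexistence state with $\hat C \le 0$ is reported as
  infeasible rather than as a negative-density equilibrium.
- **Turnover** is defined from gross assimilation,
  $(1-\delta)f(\hat R, T)$, which makes the identity turnover $= m(T)$
  exact at coexistence. Its measured shape along a branch is monotone
  increasing from the cold end (approximately exponentially); near the
  branch ends consumer *biomass* tends to zero, which is what drives
  production/biomass descriptions of a U-shape with asymptotes — the
  package reports the measured monotone curve and treats the U-shape
  phrasing as commentary about the edges, not a contract.

## What the test problems do and do not show

The test and acceptance computations run on the calibrated fixtures at the
documented sizes: 0.05 °C branch grids on [0, 40] °C (801 points), a regime
lattice of 0.25 °C × 1 °C over [0, 40] × [−25, 15] (6601 cells),
simulations of up to 3000 time units, and 20 random-initial-condition
convergence checks per model. These exercise every analytic pathway
(equilibria, eigenvalues, bifurcation detection, cycle extraction) against
independent oracles — closed forms, dense sign maps, finite-difference
Jacobians, and direct simulation. They are *not* evidence about any real
community: the fixtures emulate the structural scenario (a resource with a
wider fundamental niche than its consumer, mismatch as a pure optimum
shift, symmetric response breadths) and real systems differ in skewed
response shapes, temperature-dependent assimilation and density dependence,
behaviour, and multi-species feedbacks, none of which are modelled.

## Known limitations

- Constant environments only: no seasonal or stochastic forcing, no
  acclimation or plasticity.
- One consumer, one resource; competitors, predators and subsidies are out
  of scope, though the niche geometry extends conceptually.
- The symmetric ingestion curve understates cold-side performance relative
  to typical left-skewed empirical TPCs; realized-niche *asymmetries* here
  arise purely from the respiration exponential.
- Assimilation efficiency $1-\delta$ is temperature- and
  resource-independent.
- Breadth mismatch ($\beta_r \ne \beta$) is expressible through
  `resource_traits(beta_r = )` but is not part of the calibrated acceptance
  surface.
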