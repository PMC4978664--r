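---
title: "Delay-induced oscillations in a diffusive logistic model with feedback control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delay-induced oscillations in a diffusive logistic model with feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rdlogistic` analyses a single-species logistic population with three
regulating mechanisms: spatial diffusion, a discrete reproductive delay in
the self-limitation term, and an indirect feedback control variable. On the
habitat $\Omega = (0, l\pi)$ with no-flux boundaries (a closed habitat — no
emigration or immigration), the model is

$$
\begin{aligned}
\partial_t N &= d_1 \Delta N
  + r N\Big[1 - \frac{a_1 N + a_2 N_\tau}{K} - c\,u\Big],\\
\partial_t u &= d_2 \Delta u + b N_\tau - a u,
\end{aligned}
$$

where $N(x,t)$ is the population density, $N_\tau = N(x, t-\tau)$, and
$u(x,t)$ is a control variable produced from the delayed population at rate
$b$, decaying at rate $a$, and fed back into the growth term with weight
$c$. All ten constants are strictly positive; the delay $\tau$ is the
bifurcation parameter and is passed separately to every analysis function.

Parameter roles and units:

* $d_1, d_2$ — diffusivities (length$^2$/time). They only enter through
  $n^2/l^2$, the Laplacian eigenvalue of spatial mode $n$.
* $r$ — intrinsic growth rate (1/time); sets the overall time scale.
* $K$ — carrying-capacity scale; $a_1$ and $a_2$ split self-limitation
  between the instantaneous and the delayed population.
* $c, b, a$ — control coupling, production, and decay.
* $l$ — domain scale. Larger $l$ admits more long-wavelength modes.

Two spatially constant equilibria exist for every valid parameter set: the
(always unstable) extinction state $E_0 = (0,0)$ and the positive state

$$
N^* = \frac{aK}{a(a_1+a_2) + bcK}, \qquad u^* = \frac{b}{a}N^*.
$$

The package's reference example (`example_params()`) is
$d_1 = 1$, $d_2 = 0.5$, $r = 0.6$, $a = b = c = K = 1$, $a_1 = a_2 = 2$,
$l = 2$, for which $E^* = (0.2, 0.2)$.

```{r}
library(rdlogistic)
p <- example_params()
equilibria(p)
```

Dissipativeness gives hard a-priori ceilings: comparison with the undelayed
logistic equation bounds every nonnegative solution ultimately by
$N \le K/a_1$ and $u \le bK/(a a_1)$ (`dissipative_bounds()`); when
$a a_1 > a a_2 + bcK$ strictly, explicit positive floors also hold and the
system is permanent (`permanence()`). These are used as runtime checks on
every simulation.

## Per-mode linear analysis

With Neumann boundaries the linearization at $E^*$ splits into cosine modes
$n = 0, 1, 2, \dots$, each with a transcendental characteristic equation

$$
\lambda^2 + A_n \lambda + B_n + e^{-\lambda\tau}(C\lambda + D_n) = 0 .
$$

At $\tau = 0$ all coefficients are positive, so every mode satisfies the
Routh–Hurwitz conditions: the positive equilibrium is stable without delay
and diffusion alone cannot destabilize it (no Turing instability). A mode
can lose stability only through a conjugate pair $\pm i\omega$ crossing the
imaginary axis, which requires

$$
\omega^4 + (A_n^2 - 2B_n - C^2)\,\omega^2 + (B_n^2 - D_n^2) = 0
$$

to have a positive root. The package always forms the quadratic's
coefficients *from the coefficient values themselves*, not from any
expanded polynomial display: expanded forms of $A_n^2 - 2B_n - C^2$
circulating for this model family omit an $a^2$ term, and at the reference
parameters the expansion would give $0$ where the true value is $1.0$ —
only the latter reproduces the known frequency $\omega_0 = 0.348266$.

`mode_cutoff()` scans $Q_n = B_n^2 - D_n^2$: modes with $Q_n < 0$ admit a
unique candidate frequency; the largest such index is $N_0$. When
$a_1 \ge a_2$ the bracketed factor of $Q_n$ is strictly increasing in
$n^2$, so the first sign change is final; for $a_1 < a_2$ the scan covers
the whole range up to `n_max` (default 200) and errors if the sign has not
stabilized. Values of $Q_n$ within $10^{-12}$ of zero are classified as
"no crossing", with a warning, because the arccos branch geometry
degenerates there.

The critical delays follow from inverting the real/imaginary split of the
characteristic equation,
$\tau_0^{(n)} = \omega_n^{-1}\arccos\big[((D_n - A_nC)\omega_n^2 -
B_nD_n)/(C^2\omega_n^2 + D_n^2)\big]$, repeating with period
$2\pi/\omega_n$. The principal arccos branch is provably correct here
because $A_nD_n - B_nC > 0$ forces $\sin\omega_n\tau > 0$; the
implementation still checks the sine expression and reflects the branch if
it were negative, so the function remains correct outside the proven
regime ($a_1 < a_2$ inputs are accepted but flagged). Transversality is
available in closed form:
$\mathrm{Re}\,(d\lambda/d\tau)^{-1} = (\omega_n^4 + D_n^2 - B_n^2) /
((C\omega_n^2)^2 + (D_n\omega_n)^2) > 0$ whenever $Q_n < 0$, so each
crossing is a genuine Hopf point, and the test suite additionally verifies
the full complex derivative against Newton tracking of the root across the
crossing.

```{r}
mode_coefficients(p, 0:2)
critical_delays(p, 0, j_max = 2)   # 5.81966, 23.861, 41.9024
classify_stability(p, tau = 2)     # stable; tau0 = 5.81966
```

## The two coupling conventions

The control coupling in the linearization admits two conventions, exposed
everywhere as `coupling = c("reduced", "exact")`:

* **reduced** (default): the Jacobian entry $\partial F_1/\partial u$ is
  taken as $-cN^*$. This is the convention under which the classical
  closed-form critical quantities for this model are derived — it
  reproduces $\omega_0 = 0.348266$, $\tau_0 = 5.81966$ and the reference
  normal-form value at the example parameters, and it is what
  `classify_stability()` reports by default.
* **exact**: the entry is the true partial derivative $-rcN^*$ of the
  growth term $rN[\cdots - cu]$. The two differ by the growth-rate factor
  $r$ (they coincide when $r = 1$).

The difference is not cosmetic. The simulator integrates the nonlinear PDE
itself, whose linearization is the *exact* one: at the reference
parameters the measured oscillation onset is at
$\tau_0' \approx 8.60$ with frequency $\omega' \approx 0.2597$ (period
$\approx 24.2$), exactly as the exact-coupling analysis predicts, not at
the reduced value $5.82$. Both thresholds are consistent with the familiar
qualitative picture (steady at $\tau = 2$, periodic at
$\tau = 10, 50, 130$), which is why the discrepancy is easy to miss. The
test suite pins the simulator to the exact-coupling predictions
(onset bracketing, onset period within 5%, supercritical amplitude
growth); the reduced convention is retained as the default because the
closed-form reference numbers for this model are stated in it.

A related consequence, discovered while validating the eigenvector
machinery: for $n \ge 1$ the reduced per-mode coefficients place $d_1$
where the determinant algebra of any delayed $2\times 2$ system yields
$d_2$ (in two cross terms), so no linear system realizes them off the
homogeneous mode. `mode_coefficients()` and `critical_delays()` still
evaluate the reduced formulas for any $n$ (they are well-defined formula
evaluations and the basis of the reduced classification), but
`eigen_data()`/`normal_form()` require `coupling = "exact"` when
$n \ge 1$ and say so.

## Center-manifold normal form

At a Hopf point $(\omega^*, \tau^*)$ of mode $n$, `normal_form()` reduces
the delayed dynamics to the two-dimensional critical eigenspace and
returns $g_{20}, g_{11}, g_{02} = \bar g_{20}, g_{21}$, the first
Lyapunov-type coefficient

$$
c_1(0) = \frac{i}{2\omega^*\tau^*}\Big(g_{20}g_{11} - 2|g_{11}|^2 -
\tfrac13|g_{02}|^2\Big) + \frac{g_{21}}{2},
$$

and the indices $\mu_2 = -\mathrm{Re}\,c_1(0)/\mathrm{Re}\,\lambda'(\tau^*)$
(direction: supercritical iff $\mu_2 > 0$), $\beta_2 = 2\,\mathrm{Re}\,c_1(0)$
(orbital stability: stable iff $\beta_2 < 0$) and $T_2$ (period trend).

Three readings in the circulating closed-form coefficient set for this
model had to be fixed before the chain was internally consistent; each is
forced by a mathematical requirement and verified by a dedicated test:

1. **The left eigenvector component.** The adjoint null-vector condition
   forces $\eta = -cN^*/(i\omega^* + a)$; the same expression with a $+$
   sign (which also circulates) is not a left eigenvector, and with it the
   real part of $c_1(0)$ comes out positive — contradicting both the
   reference value and the stable periodic orbits the simulator exhibits.
   `eigen_data()` verifies both eigenvector residuals to $10^{-8}$ and the
   bilinear-pairing normalization $(q^*, q) = 1$ to $10^{-9}$.
2. **The constant term in $W_{11}(\theta)$** is read as $q(\theta)$, the
   only reading under which $W_{11}$ is self-conjugate (its evaluations at
   $\theta = 0, -1$ must be real for the homogeneous mode; asserted to
   $10^{-9}$).
3. **A doubled superscript in the cubic projection** is read as the first
   component of $W_{11}(-1)$, the only dimensionally coherent choice.

Two projection schemes are provided. `projection = "reference"` (default)
evaluates the classical coefficient set as published for this model family
(with the three readings above); it reproduces the reference value
$\mathrm{Re}\,c_1(0) \approx -1.43$ at the example parameters. Notably,
that value is only obtained when the quadratic projections
$g_{20}, g_{11}, g_{21}$ are taken *without* the delay prefactor
$\tau^*$ that a fully rescaled-time derivation carries — an exhaustive
search over the scaling conventions shows no other combination lands on
the reference number, so the reference scheme reconstructs that
convention. `projection = "rederived"` is the package's own standard
$z^2/2$-expansion reduction with all $\tau^*$ factors; at the example
parameters it gives $c_1(0) \approx -2.81 - 13.48i$. The two schemes — and
both couplings — always agree in the *signs* of
$\mathrm{Re}\,c_1(0), \mu_2, \beta_2$, hence in the classification, which
for the example is: supercritical, orbitally stable, period increasing
with the delay. The imaginary part of $c_1(0)$ is the one quantity on
which the conventions disagree materially; the package reports whatever
the selected scheme yields and makes no claim that a particular published
imaginary value is recoverable. The quadratic projections of the
rederived scheme are cross-checked in the tests against a
finite-difference Hessian oracle of the reaction term, per the
$z^2/2$ convention (the quadratic Taylor coefficients at $E^*$ are
$-ra_1/K$, $-ra_2/K$, $-rc$; a doubled first coefficient that sometimes
appears in displays of the nonlinearity is not consistent with direct
expansion and is not used).

For $n \ge 1$ the quadratic projections vanish (cosine orthogonality), so
$c_1(0) = g_{21}/2$ structurally; spatial averages of $\cos^2(nx/l)$ are
resolved in closed form ($1$ for $n=0$, $1/2$ otherwise) but the scalar
treatment ignores mixing into modes $0$ and $2n$, so those results carry
`validated = FALSE` and are excluded from every quantitative claim.

```{r}
hp <- critical_delays(p, 0)[1, ]
normal_form(p, hp)                              # reference scheme
glance(normal_form(p, hp, projection = "rederived"))
```

## The simulator

`simulate_rd()` integrates the full PDE by the method of lines:

* node-centered grid of `M` points on $[0, l\pi]$, endpoints included
  (default $M = 101$); Neumann conditions by second-order mirror ghost
  nodes;
* classical RK4 in time with a *fixed* step chosen at or below the
  explicit diffusion limit $h^2/(2\max(d_1,d_2))$ (conservative for RK4)
  and then shrunk so $\tau/\Delta t$ is an exact integer — the delayed
  field is then a plain ring-buffer index with no interpolation error at
  whole steps (half-step stages average two adjacent slots, a second-order
  treatment consistent with the spatial order);
* the history on $[-\tau, 0)$ defaults to the constant extension of the
  $t = 0$ data, the natural reading when only an initial pair is
  prescribed; arbitrary nonnegative history functions are accepted;
* runs abort with a diagnostic if a field exceeds ten times its
  dissipative ceiling or becomes non-finite; nonnegativity and the
  ceilings themselves are asserted in the tests, not silently enforced;
* no random numbers anywhere; repeated runs are bit-identical.

`oscillation_summary()` classifies the trailing window (default 30%) of
the population series at the domain midpoint. Steadiness means
peak-to-trough amplitude below $10^{-3}$ in field units. Otherwise the
period is estimated from *mid-level upcrossings* rather than local maxima:
at large delays the model produces flat-topped relaxation oscillations
(the orbit rides the dissipative ceiling $K/a_1$, then collapses near
zero), on which derivative-based peak detection fails while level
crossings remain well defined. "Periodic" requires at least three
upcrossings with under 10% dispersion in the intervals; otherwise the
window is declared too short ("undetermined").

Problem sizes used by the shipped tests: $M = 101$ for the four headline
runs ($\tau = 2, 10, 50, 130$; horizons 400–3000 time units, the longest
covering four relaxation cycles of period $\approx 326$ at $\tau = 130$),
and $M = 21$ for the homogeneous-dynamics checks (constant-in-space data
make the spatial resolution irrelevant there, and the temporal step is
still delay-locked). Grid-refinement tests confirm the steady-state error
and the measured period move by under 1% between $M = 51$ and $M = 101$.

What the simulations do and do not show: they verify the analytical
predictions for *this* model — onset location, onset period, supercritical
amplitude growth, boundedness, spatial homogenization of constant data —
under constant histories and the reference-scale parameters. They do not
probe spatially structured attractors (the destabilizing mode of the
reference set is homogeneous), stochastic effects, non-constant
diffusivities, or multi-species interactions; none of those are modeled.

```{r}
delay_sweep(p, taus = c(2, 10, 50, 130), t_end = 3000,
            window_fraction = 0.5)
```

## Numerical choices and degenerate inputs

* Quartic-in-$\omega$ roots with $|Q_n| < 10^{-12}$: treated as no
  crossing, with a warning (tie-break toward stability).
* `classify_stability()` returns `"at_bifurcation"` within $10^{-9}$ of
  $\tau_0$ rather than forcing a stable/unstable verdict.
* Eigenvector denominators and center-manifold matrices are
  singularity-checked ($10^{-12}$ thresholds); the resonant case cannot
  occur for valid parameters but is guarded.
* $a_1 < a_2$ inputs: two candidate frequencies per mode become possible
  and the stable-below/unstable-above picture need not hold; all roots
  are reported and results carry an explanatory note instead of a
  classification claim.
* Permanence is a sufficient condition only; `FALSE` makes no claim of
  non-permanence. Its proof-level constants involve intermediate
  time-threshold bookkeeping that the package does not reproduce; only
  the final inequalities and bounds are implemented.

## Known limitations

* The first delay interval is the only one classified; no root
  continuation past the first crossing, and no global continuation of the
  bifurcating branch is attempted (empirically the periodic solutions
  persist to at least $\tau = 130$ at the reference parameters).
* Normal forms for inhomogeneous modes are structural only (see above).
* The reduced/reference conventions are reproduced as published for
  comparability; where they conflict with first-principles derivations,
  both are available and the differences are documented here rather than
  silently resolved.
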