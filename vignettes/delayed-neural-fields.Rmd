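---
title: "Stability of delayed neural fields: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability of delayed neural fields: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`delayfield` analyzes scalar neural field equations with space-dependent
propagation delays,

$$\partial_t V(t,x) \;=\; -\ell\, V(t,x)
 + \int_\Omega J(x-y)\, S_0\!\big(\sigma\, V(t-\tau(x,y),\,y)\big)\, dy
 + I_{ext}(x),$$

describing the mean membrane potential of a neural population on a
one-dimensional ring $\Omega$. The leak rate $\ell$ pulls the potential back
to rest, the even kernel $J$ mixes excitation and lateral inhibition, the
sigmoid $S_0$ (odd, $S_0(0)=0$, slope $s_1$ at the origin) converts
potential into firing rate with gain $\sigma$, and the axonal delay is
proportional to distance, $\tau(x,y) = c\, d(x,y)$, with $c$ the inverse
propagation speed. Because axons are nearly straight, distance-proportional
delays are the physiologically natural choice; $\tau_m = c \cdot
\mathrm{period}/2$ is the maximal delay.

The reference configuration used throughout the package ships as a fixture
(`make_fixtures()`): unit leak, $J(z) = -1 + 1.5\cos 2z$ on the ring of
circumference $2\pi$, centered logistic sigmoid with $s_1 = 1/4$. The
kernel's positive Fourier coefficient sits on mode $k=2$
($\hat J_2 = 1.5\pi$), so patterns with two bumps form first; the mean mode
is inhibitory ($\hat J_0 = -2\pi$), which is what the delays can
destabilize into oscillations.

A note on conventions: the ring has circumference $2\pi$ and the delay
metric is the geodesic distance, so the delay function plotted over one
period is the familiar saw-like triangle with peak $c\pi$. The kernel is
$\pi$-periodic, but the delay is only $2\pi$-periodic; consequently *odd*
Fourier modes, whose non-delayed gains vanish by orthogonality, still
couple to the dynamics once $\lambda c \neq 0$. All spectral routines
therefore scan integer modes, not only the even ones carried by the kernel.
This convention is not cosmetic: it is what places the fold--Hopf point of
the reference model at $c^\ast \approx 3.65$ (see below); halving the
period moves it to $3\pi/4$, which is a different model.

## Stationary states and their stability

Stationary (persistent) states satisfy $-\ell V + J * S_0(\sigma V) +
I_{ext} = 0$ and are *identical with and without delays*;
`find_stationary()` locates them by damped Newton iteration from several
starts. The question the package answers is how the delays change the
*stability* of each state. Three independent routes are implemented, in
increasing order of cheapness and conservatism:

1. **Characteristic values (exact).** Linearizing about $V^f$ gives a delay
   operator whose spectrum consists of the essential part $\{-\ell\}$
   plus eigenvalues ("characteristic values", CVs) — roots of
   $$\Delta_k(\lambda) = \lambda + \ell - \sigma S_0'(\sigma V^f)
   \int_\Omega J(z)\, e^{-\lambda c\, d(z)} \cos(kz)\, dz$$
   per Fourier mode $k$ on the homogeneous ring. Only finitely many CVs lie
   right of $-\ell$; the state is asymptotically stable iff the spectral
   abscissa (largest real part) is negative. `solve_mode_roots()` finds the
   roots by complex Newton iteration; `build_generator_matrix()`
   independently discretizes the infinitesimal generator and takes matrix
   eigenvalues. Either method can serve as the other's oracle, and
   `assemble_spectrum(method = "both")` refuses to answer if they disagree.

2. **Delay-dependent bound (cheap, conservative).** If the state is stable
   *without* delays (decay rate $\epsilon > 0$), a contraction argument
   certifies stability for all delays with
   $K(\beta) = (1 + M_\epsilon\|\tilde L\|/\epsilon)\,
   \tau_m^{1+\beta}\, \|\tilde J\, \tau^{-\beta}\|_{HS} < 1$
   for some admissible exponent $\beta > 0$. Small delays never
   destabilize; `max_stable_delay_scale()` returns the certified range of
   $c$ (exactly linear in $c$ on the ring).

3. **Delay-independent bound (cheapest, most conservative).** If
   $\|\tilde J\|_{HS} < \ell$ the state is stable for *every* delay
   function, and the dynamics are globally trivial.

## The two spectral methods and their numerics

**Per-mode characteristic roots.** For cosine-series kernels the delayed
transform $\int J(z) e^{-\lambda c |z|} \cos(kz)\,dz$ has a closed form
built from $\int_0^L e^{-az}\cos(bz)\,dz$, analytic in $\lambda$, with an
analytic derivative; Newton iteration is started from a rectangular grid
covering $\mathrm{Re}\,\lambda \in [-\ell-1, 2]$,
$\mathrm{Im}\,\lambda \in [0, \omega_{\max}]$ with
$\omega_{\max} = \max(20, 10/(\tau_m + 0.1))$ — delay-induced roots have
imaginary parts scaling like $1/\tau_m$, so the window widens as delays
shrink. Converged roots are kept below residual $10^{-10}$ and
deduplicated at $10^{-6}$; multiplicities are *not* resolved (nearby roots
are reported as distinct). Conjugate pairs are stored once, by their
upper-half representative. The test suite checks the root counts against
an argument-principle winding oracle on sample rectangles.

**Discretized generator.** The generator acts on history segments
$u(\theta, x)$, $\theta \in [-\tau_m, 0]$, as $d/d\theta$ away from
$\theta = 0$ and as the delayed operator at $\theta = 0$. We collocate
$\theta$ at Chebyshev–Gauss–Lobatto points (spectral differentiation
matrix, barycentric interpolation at the lags $-\tau(x,y)$) and the ring
at uniform nodes. One numerical subtlety matters: the ring distance has a
kink at coincidence and at the antipode, so a plain trapezoid rule for the
boundary integral is only second-order accurate and would cap the
attainable cross-method agreement far above the $10^{-6}$ we require. For
homogeneous models the boundary integral is therefore assembled from
Gauss–Legendre panels on the two smooth arcs on either side of the kink,
with trigonometric interpolation back to the uniform nodes; this restores
spectral accuracy (the cross-method tests pass at $10^{-8}$ with a
$32$-node grid). Tabulated (inhomogeneous) models fall back to the
trapezoid rule, which is documented and acceptable for survey work but not
for tight cross-validation.

With `n_space = 160`, `m_delay = 24` the eigenvalue sequence of the
reference model (delays at $c = 1$) reproduces the accumulation of the CVs
at the essential spectrum: the median real part of eigenvalues 151–200 is
$-1.007$, with median imaginary part at rounding level. We deliberately
report the *median* of the trailing block: a handful of genuine
delay-chain roots with real parts near $-1.05$ and imaginary parts up to
$\approx 4$ interleave with the accumulating sequence, and the median is
robust to them while a maximum would not be.

## The contraction constant

The delay-dependent condition is assembled in one pure function,
`contraction_constant()`, from its proof: writing the delayed
linearization as the non-delayed one plus $\frac{d}{dt}Z(t)$ with
$Z(t) = \int_\Omega \tilde J(x,y) \int_{t-\tau(x,y)}^{t} U(s,y)\, ds\, dy$,
Cauchy–Schwarz in time and space gives
$\|Z(t)\| \le \tau_m^{1+\beta}\, \|\tilde J\,\tau^{-\beta}\|_{HS}
\sup_{[t-\tau_m,t]}\|U\|$ for every $\beta > 0$ such that
$\tau^{-\beta}$ is square-integrable against the kernel, and the
variation-of-constants formula turns this into the contraction constant
$K(\beta)$ quoted above. Three properties of $K$ — not its constant
factors — carry all the scientific weight, and they are what the
acceptance suite pins down: $K$ certifies only CV-stable points
(sufficiency, checked on a $20\times 20$ parameter grid with zero
violations allowed), $K$ is nondecreasing in $\tau_m$ at fixed $\beta$,
and $K \to 0$ as $c \to 0$, so every state that is stable without delays
admits a strictly positive delay scale.

Admissibility of $\beta$ is dimension-dependent. On the 1-D ring,
$\tau^{-2\beta} \sim |z|^{-2\beta}$ is integrable only for $\beta < 1/2$
when $J(0) \neq 0$; the scanned grid (40 log-spaced points in
$[10^{-3}, 0.999]$) simply skips inadmissible exponents, and in practice
the minimizer sits at the small-$\beta$ end. On a planar domain the cap is
$\beta < 1$: `disk_power_integral_converges()` verifies this numerically
by reducing the pair integral over the unit disk to a radial integral via
the disk covariogram and refining the inner cutoff geometrically — the
increment-decay exponent is $2 - 2\beta$, so its sign decides convergence
with no fitted tolerance doing hidden work. The bisection
`disk_integrability_threshold()` returns $1.000 \pm 10^{-3}$.

The certified verdicts use the Hilbert–Schmidt norm throughout (that is
the quantity the Cauchy–Schwarz estimates control); the sharper operator
norm is computed and reported alongside but never used for certification.

## Bifurcation curves

Because the mode gain is linear in $\sigma$, a purely imaginary root
$\Delta_k(i\omega) = 0$ can be solved by *eliminating* $\sigma$: $\omega$
must be a zero of a single real function, and $\sigma$ follows by division.
We use this elimination (a scan plus bisection per mode) rather than the
more generic damped two-variable Newton with continuation: it is exact for
the homogeneous ring, has no basin-of-attraction failures, and finds *all*
branches in the frequency window rather than the one a warm start happens
to track. The generic generator matrix remains available as a spot check.
The Hopf curve `hopf_curve()` retains, per delay scale, the minimal gain
over modes and branches; the pitchfork line is vertical at
$\sigma_0 = \ell/(s_1 \max_k \hat J_k)$ because $\lambda = 0$ kills the
delay dependence. `fold_hopf()` brackets $\sigma_H(c) = \sigma_0$ on a
coarse scan and bisects; for the reference model
$c^\ast = 3.650$, $\omega^\ast = 0.471$, carried by the uniform
(mode-0) pair against the mode-2 pattern. $c^\ast$ is invariant under the
sigmoid slope normalization — gain and slope enter only as a product —
and the test suite verifies this gauge invariance numerically.

## The simulator

`integrate_field()` integrates the full nonlinear equation by a
method-of-steps RK4: within a step, every delayed value is read from the
cubic Hermite interpolant of the accepted samples (the exact initial
history below $t = 0$), and the vanishing diagonal delay
$\tau(x,x) = 0$ is served by extrapolating the last Hermite segment — a
local predictor whose error is buried in the quadrature weight of a single
node. Without delays the scheme reduces to classical RK4 exactly (the
suite checks this against an independent ODE solver to $10^{-10}$). Formal
order is not claimed for the delayed path; the suite *measures*
self-convergence and observes better than first order (in practice close
to second) on the reference model, which is all the qualitative
regime-classification work requires. A blow-up guard aborts when the norm
exceeds $100 \max(R, 1)$, with $R$ the ultimate bound
$(\sqrt{|\Omega|}\,\|J\|_{L^2(\Omega^2)} + \|I_{ext}\|)/\ell$ — every
trajectory eventually enters the ball of radius $R$ regardless of delays,
and the ensemble tests verify no seeded trajectory ever exceeds $1.05 R$
after the transient.

Initial conditions for all experiments are random in space and constant in
time: node-wise uniform draws in $[-0.1, 0.1]$ from a recorded seed
(`random_history()`). This emulates unstructured spontaneous activity near
rest and is the configuration under which the three regimes of the
stability diagram are reproduced: monotone decay below all curves,
convergence to a two-bump stationary pattern beyond the pitchfork line,
and sustained oscillation beyond the Hopf curve. What these synthetic
histories do *not* emulate is structured or noisy ongoing input, spatial
heterogeneity, or multi-population interactions — passing tests say
nothing about those regimes, and the package scope is deliberately the
scalar (one-population) ring with deterministic dynamics.

## Problem sizes and tolerances

Defaults were chosen so every analysis runs on a laptop core: 48–64 ring
nodes for simulation and root solving, 160 nodes and Chebyshev degree 24
for the accumulation study (a dense $4000^2$ eigenproblem, under a
minute), $dt = 0.02$ for regime classification at horizons up to
$t = 200$, and 20-seed ensembles at 32 nodes for the boundedness checks.
Stationary-state residuals are accepted below $10^{-11}$ (weighted $L^2$),
characteristic roots below $10^{-10}$ with $10^{-6}$ deduplication, and
the stability verdict is three-valued with a $10^{-6}$ marginality band on
the abscissa so the package does not overclaim at bifurcation points.

## Known limitations

* One population ($p = 1$); the linear algebra generalizes but is not
  implemented.
* Inhomogeneous (tabulated) models get the generator route only, at
  trapezoid accuracy; no analytic characteristic equation exists there.
* The Hopf curve is a locus of purely imaginary CVs; normal-form
  coefficients are not computed, so sub/supercriticality is inferred from
  simulation, not proved.
* The delay-dependent certificate is conservative by one to two orders of
  magnitude in $c$ on the reference model — the exact margin is visible in
  the stability maps, where both certified regions sit well inside the
  CV-stable region.
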