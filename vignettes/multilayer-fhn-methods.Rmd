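---
title: "Methods: FitzHugh-Nagumo dynamics on multilayer networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FitzHugh-Nagumo dynamics on multilayer networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fhnnet)
```

## The model

`fhnnet` analyses the FitzHugh-Nagumo (FHN) excitable-neuron model

$$\frac{du}{dt} = c\left(u - \frac{u^3}{3} - a v + I\right), \qquad
  \frac{dv}{dt} = c\,(b u - v + d),$$

where $u$ is the fast membrane potential, $v$ the slow recovery
variable, $I$ an external input current, $a$ and $b$ the mutual
coupling intensities of the two variables, and $c \ne 0$ a timescale
constant. Identical FHN units sit on the nodes of a *Cartesian-product
network* $R \,\Box\, E$: two layers $R$ and $E$ (here Erdős–Rényi
graphs $G(n, p)$) whose product Laplacian is the Kronecker sum
$L^{R\Box E} = L^R \otimes I + I \otimes L^E$. Throughout the package
the Laplacian convention is $L = A - \mathrm{diag}(k)$, so $L$ is
negative semidefinite and all eigenvalues satisfy $\Lambda \le 0$. The
product spectrum is exactly the grid of pairwise sums
$\Lambda^R_\alpha + \Lambda^E_\beta$, which is what makes the
multilayer dispersion analysis tractable: every stability question
reduces to a scalar function of the pair
$(\Lambda^R_\alpha, \Lambda^E_\beta)$.

The package covers four layers of analysis plus simulation:

1. **Equilibria and local stability** (`fhn_model`, `linearize`,
   `check_h1`). Equilibria solve the cubic
   $u^3 + 3(ab-1)u + 3(ad-I) = 0$; the discriminant
   $\Delta = \varrho^2 + (ab-1)^3$ with $\varrho = \tfrac32(ad-I)$
   decides between one, two, or three real roots (and the degenerate
   triple-zero root when $ab = 1$, $ad = I$). Roots are computed by
   closed-form Cardano in complex arithmetic, then polished with a few
   Newton steps; the complex route avoids sign-branch errors near case
   boundaries. The equilibrium is locally stable without diffusion iff
   $c u^{*2} > 0$ and $u^{*2} + ab - 1 > 0$ (Routh–Hurwitz on the
   $2\times 2$ Jacobian).

2. **Turing instability** (`h2_value`, `classify_spectrum`,
   `critical_dv`). Diffusion of strength $D_u, D_v$ (possibly
   layer-specific) destabilizes the mode
   $(\Lambda^R_\alpha, \Lambda^E_\beta)$ iff a quadratic form in the
   two eigenvalues is negative; with layer-equal coefficients it
   reduces to the dispersion curve
   $y(\Lambda) = \Delta_0 + (a_{22}D_u + a_{11}D_v)\Lambda +
   D_uD_v\Lambda^2$ in the eigenvalue sum. In the continuous
   relaxation, instability first occurs when
   $a_{22}D_u + a_{11}D_v > 0$ and the discriminant of $y$ turns
   positive; `critical_dv` returns the resulting threshold in $D_v$ at
   fixed $D_u$ (about $8.396$ at the reference parameters with
   $D_u = 0.01$). Because an actual network offers only a discrete set
   of eigenvalue sums, the package also provides
   `network_critical_dv`, the smallest $D_v$ at which some *actual*
   eigensum turns unstable; it is never below the continuous
   threshold.

3. **Delay-induced Hopf bifurcation** (`characteristic_coeffs`,
   `solve_hopf`, `tau0_over_spectrum`). Delaying the cross-coupling
   term $a_{12} v(t-\tau)$ gives each mode the transcendental
   characteristic equation
   $\lambda^2 + B_1\lambda + B_2 + B_3 e^{-\lambda\tau} = 0$. On the
   imaginary axis this collapses to the quadratic $x^2 + px + q = 0$
   in $x = \omega^2$; in the regime $q < 0 < p$ there is exactly one
   crossing frequency $\omega_0$, and the threshold $\tau_0$ is the
   smallest positive delay solving the simultaneous sine/cosine
   conditions. Two numerical points deserve note. First, the crossing
   angle is computed with `atan2` and wrapped to $[0, 2\pi)$: a bare
   arccosine silently assumes $\sin(\omega_0\tau_0) > 0$, which holds
   at the reference parameters but not for general coefficient signs.
   Second, the branch index is taken to start at $j = 0$, i.e. the
   threshold is the smallest positive crossing; this is required for
   the statement "all roots stable for $\tau < \tau_0$" to hold.
   The transversality derivative uses the exact closed form
   $d\lambda/d\tau = B_3\lambda e^{-\lambda\tau} /
   (2\lambda + B_1 - B_3\tau e^{-\lambda\tau})$, never a finite
   difference; the tests cross-check it against Newton continuation of
   the root.

4. **Center-manifold normal form** (`hopf_eigvectors`, `solve_ell`,
   `normal_form`). At $(\,\pm i\omega_0, \tau_0)$ the delayed system
   is reduced by the Hassard procedure to
   $\dot z = i\omega_0\tau_0 z + g(z,\bar z)$; from $g_{20}, g_{11},
   g_{02}, g_{21}$ the first Lyapunov-type coefficient $c_1(0)$ and
   the bifurcation quantities follow: direction
   $\mu_2 = -\mathrm{Re}\,c_1(0)/\mathrm{Re}\,\lambda'(\tau_0)$,
   Floquet exponent $\beta_2 = 2\,\mathrm{Re}\,c_1(0)$, period
   correction $T_2$. At the reference parameters the single-node Hopf
   point is subcritical ($\mu_2 < 0$) with orbitally unstable periodic
   solutions ($\beta_2 > 0$).

## The two nonlinearity variants

Shifting coordinates to the equilibrium turns the cubic rate law into
$f(u) = Q u^2 + C u^3$ plus linear terms. Direct Taylor expansion of
the model gives $Q = -c\,u^*$, $C = -c/3$. The normal-form literature
for this system, however, states the shifted nonlinearity *without*
the factor $c$: $Q = -u^*$, $C = -1/3$. The two conventions give
identical linear analysis (the Jacobian is unaffected) but different
normal-form magnitudes: the quadruple
$(\mathrm{Re}\,c_1(0), \mu_2, \beta_2, T_2)$ scales roughly with the
nonlinearity. Both variants are implemented behind
`linearize(..., variant =)`:

* `"printed"` (default) uses $Q = -u^*$, $C = -1/3$ and reproduces the
  reference quadruple $c_1(0) \approx 0.021 - 0.273i$,
  $\mu_2 \approx -0.021$, $\beta_2 \approx 0.042$,
  $T_2 \approx 0.162$;
* `"c-scaled"` uses $Q = -c\,u^*$, $C = -c/3$, the analytically
  consistent expansion of the stated equations, and yields
  $c_1(0) \approx 0.474 - 1.503i$.

Both classify the reference Hopf point as subcritical with orbitally
unstable periodic solutions; only the magnitudes differ. The default
follows the printed convention so that the package's numbers are
directly comparable with the reference values; users who want the
Taylor-consistent scaling switch the flag.

```{r variants}
nf_p <- normal_form(linearize(fhn_model(), variant = "printed"))
nf_c <- normal_form(linearize(fhn_model(), variant = "c-scaled"))
c(printed = nf_p$c1_0, c_scaled = nf_c$c1_0)
```

## Numerical choices

* **Zero tests.** Discriminant-case boundaries use absolute tolerance
  $10^{-12}$. Parameters are user-supplied exact values, so inputs
  within the tolerance of a boundary are classified to the boundary
  case rather than to an arbitrary open case.
* **Strictness.** Both the stability test and the Turing criterion are
  strict inequalities; equality is marginal, reported as stable /
  not-unstable respectively.
* **Eigen-decompositions** use the dense symmetric solver
  (`eigen(symmetric = TRUE)`); layer spectra are stored descending so
  the leading entry is the structural zero.
* **Crossing-regime policy.** `solve_hopf` implements exactly the
  single-positive-root regime ($q < 0 < p$); any other sign pattern
  returns `exists = FALSE` with the failing condition named, as a
  value rather than an error, so spectrum-wide sweeps skip those modes
  cleanly.
* **Degenerate linear systems.** The two $2\times2$ systems for the
  center-manifold constants $\ell_1, \ell_2$ are checked for
  singularity (resonance) and raise errors naming the offending
  system.

## Integrators

Fixed-step schemes are used deliberately — reproducibility of delayed
and stochastic paths under seeding outweighs adaptivity here:

* deterministic, undelayed: classical RK4;
* delayed: explicit Euler by the method of steps with a ring history
  buffer and linear interpolation at off-grid lags; the pre-history is
  constant, $v(t) = v(0)$ for $t \in [-\tau, 0]$;
* stochastic: Euler–Maruyama; each node's $u$ receives an independent
  Gaussian increment of standard deviation $np\sqrt{dt}$ per step
  (additive, Itô). Noise enters only the $u$ equation.

Defaults are $dt = 0.005$, $t_\mathrm{end} = 200$. The RK4 path is
validated against an adaptive reference integrator and by step-halving
(terminal-state change below $10^{-4}$ relative). For stiff
simulations (large $D_v$ times extreme eigenvalues) the explicit
stability bound $dt \lesssim 2.5/\max|a_{22} + D_v\Lambda|$ governs
the step choice.

Seeding uses one base seed per run with fixed substream offsets for
layer generation, initial perturbation and noise, so changing the
horizon never changes the generated graphs or the perturbation draw.

**Initial perturbations act on $u$ only.** Every exogenous drive in
this model — input current, stimulus, noise — acts on the membrane
potential, so the "equilibrium plus perturbation" initial state
perturbs $u$ alone (i.i.d. uniform on $[-10^{-2}, 10^{-2}]$ by
default) and leaves $v$ at its equilibrium value. This matters in the
delayed, strongly $v$-coupled regime ($\tau = 1$, $D_v = 8$, dense
layers), where the system is bistable between a synchronized
oscillation and a frozen heterogeneous pattern: perturbing $v$
directly often selects the frozen attractor, i.e. it probes basin
geometry rather than the delay-induced collective oscillation these
experiments study.

## What the synthetic-data generator emulates

Layer graphs are simple undirected $G(n,p)$ draws, exactly as in the
study design: no connectivity enforcement, no rejection sampling —
at $p$ as small as $0.001$ layers are usually mostly isolated nodes,
which is a legitimate and analytically interesting regime (the product
spectrum then concentrates near 0). Real cortical networks are not
Erdős–Rényi: they have modules, hubs, degree heterogeneity and
geometry. Passing tests therefore demonstrate the mechanism
(spectrum-driven pattern onset, delay-induced oscillation, synchrony
growing with coupling density) on the stated random-graph ensemble,
not on brain connectomes.

Because the reference study does not state its graph seeds, exact
pattern matrices are not reproducible; all pattern-level checks are
statistical or qualitative: prediction/simulation agreement of Turing
onset over a seeded fixture grid, order-of-magnitude noise-robustness
brackets, and monotone synchrony medians across $p$.

## Study sizes used by the test suite

The packaged experiments are scaled to the package's test design:
Turing-onset agreement uses 24 fixtures (8 $(D_v, p)$ combinations
$\times$ 3 seeds) on $20 \times 20$-node products with
$t_\mathrm{end} = 600$ and the stability-bound step; onset is declared
when the cross-node standard deviation of $u$ grows tenfold. Noise
robustness compares $np = 10^{-7}$ against $10^{-4}$ over 5 seeds at
$t_\mathrm{end} = 50$. The synchrony sweep runs $\tau = 1$,
$p \in \{0.01, 0.1, 0.3\}$ over 5 seeds at $t_\mathrm{end} = 100$,
with the index computed over the terminal quarter of each run. These
sizes resolve the qualitative contrasts cleanly while keeping the full
suite fast.

## Known limitations

* The Turing analysis assumes a stable base state; functions warn or
  abort when the no-diffusion stability test fails.
* Only the delay placement on the cross-coupling term
  $a_{12}v(t-\tau)$ is supported; diffusion is never delayed.
* The normal form is second-order in the Hassard hierarchy; the
  $W_{02}$ block and fifth-order corrections are not computed (not
  needed for $g_{21}$ or the quadruple).
* Growth-based onset detection has finite resolving power: a mode
  whose dispersion value is barely negative grows too slowly to
  trigger the tenfold criterion within any practical horizon. The
  test design treats fixtures whose eigensums graze the window
  boundary (within 1% of the window width) as marginal and does not
  adjudicate them.
* Weighted, directed, or non-product couplings are out of scope, as
  are scale-free/small-world generators and parameter estimation from
  recordings.
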