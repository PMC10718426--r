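---
title: "Methods: spatial-exclusion competition in one-dimensional microchannels"
author: "tugofwar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-exclusion competition in one-dimensional microchannels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tugofwar)
```

## The model

Two cell species share a one-dimensional open channel of `N` lattice sites
(think of *E. coli* growing single-file in a microfluidic chemostat lane).
The channel is always full.  A cell can divide anywhere; to make room, the
daughter pushes every cell between itself and one channel opening a site
over, and the terminal cell on that side falls out.  Death therefore
happens only by expulsion, and the composition changes only when the
expelled cell belongs to the other species than the divider.

Two ingredients set the rates:

* **Fitness-weighted selection.**  A cell of species 1 is picked for
  division with weight `w` (relative fitness, `w = 1 + s`), a cell of
  species 2 with weight 1; the total weight is `D = (N - n) + w n` where
  `n` is the species-1 abundance.
* **Linear direction bias.**  A cell at position `i` grows toward the
  right opening with probability `(i - 1)/(N - 1)` — proportional to the
  number of cells it would have to displace to the left, as observed in
  open-channel experiments.  Cells push preferentially toward the nearer
  exit.

With both species segregated (species 1 occupying positions `1..n`), the
inter-species boundary performs a birth–death walk on `n = 0..N` with

$$r^+(n) = \frac{r\,w\,n(n-1)}{2[(N-n)+wn]}, \qquad
  r^-(n) = \frac{r\,(N-n)(N-n-1)}{2[(N-n)+wn]},$$

obtained by summing the per-cell division rates over each species block
(`spatial_rates()`).  The factors `n(n-1)` make the edge states one-way:
a lone cell at a wall can never divide inward, so `n = 1` is certain
extinction and `n = N - 1` certain fixation.  The classical Moran model
(`moran_rates()`) is kept alongside as the well-mixed baseline.

**Time convention.**  The basal rate defaults to `r = 1`, under which the
whole channel performs `r (N - 1)` divisions per unit time and the Moran
chain is scheduled at `N` events per unit time — both roughly one
generation per unit time, so fixation-time curves of the two models are
directly comparable.  `r` only rescales time everywhere.

**Why `N >= 3`.**  At `N = 2` both boundary rates vanish at the single
interior state (each species is a lone edge cell) and the `(N - 1)`
normalisation of the direction bias degenerates; the constructor refuses
rather than regularise a frozen chain.

## Exact first-passage solvers

`fixation_probability()` solves the backward equation by the
gambler's-ruin product form with the rate-ratio products accumulated in
log space (`logsumexp`-style cumulative sums), which is stable at least up
to `N = 10^4`.  Structural zeros are short-circuited exactly: states at or
below the last zero up-rate inherit certain extinction, mirrored at the
top; an interior state with no outgoing rate raises an error.  The
species-2 probability is computed independently on the mirrored chain, so
the unit-sum identity is a genuine cross-check rather than a tautology.

`mfpt_unconditional()` solves the tridiagonal backward system with a
direct sparse solve (O(N)); `mfpt_conditional()` uses the standard
construction `g = P_target * tau_target` with source `-P_target`, dividing
only where the conditioning probability is positive and reporting `NA`
elsewhere — a state that cannot reach the target has no conditional time,
not a zero one.  Averages over initial conditions
(`average_over_initials()`) run over interior states only; the absorbing
ends are not competitions.

## Continuum description

With `f = n/N`, drift `A(f)` and diffusion `B(f)` are the continuum limits
of `r^+ - r^-` and `r^+ + r^-`.  The spatial drift vanishes at a single
interior point, the equiprobable takeover abundance

$$f_{eq} = \frac{1}{1 + \sqrt{w}},$$

the positive root of `(w-1)f^2 + 2f - 1`.  The Fokker–Planck potential

$$U(f) = -2N\int^f \frac{A(y)}{B(y)}\,dy$$

is unimodal with an unstable maximum at `f_eq` (a peak, not a well: the
escape problem is a descent from an unstable point, where saddle-point
machinery for barrier crossing does not apply).  The integrand is a
rational function, so `fp_potential()` uses its closed-form antiderivative
(linear + logarithm + arctangent after partial fractions) rather than
numerical quadrature: exact, cheap inside nested solves, and verified in
the tests against adaptive quadrature of `A/B`.  `U` is normalised to
`U(f_eq) = 0` and all `exp(U)` ratios are formed with the peak subtracted,
keeping every weight at or below 1 regardless of `N`.

`fp_fixation_probability()` evaluates the classical two-boundary formula
`P1(f) = ∫_0^f e^U / ∫_0^1 e^U` by cumulative trapezoidal quadrature on a
mesh refined around the peak (the integrand mass concentrates in a window
of width `~ |U''(f_eq)|^{-1/2} ~ N^{-1/2}`; the refinement window spans 30
such widths with 2001 points on top of a 4001-point uniform base).

`fp_mfpt()` solves the continuum backward boundary-value problem directly
by sparse central finite differences.  The mesh spacing scales as
`1/(20N)` (capped at 40001 nodes) so the cell Péclet number
`h N |A/B|` stays well below 1 and central differencing needs no
upwinding.  The quadrature representation with `e^{±U}` factors is not
used as the primary path: the direct solve is simpler, and the exact
discrete solver — not the continuum one — is what the package uses
wherever large-`N` precision matters.

## Deterministic time, the tug-of-war region, and log-N scaling

Away from `f_eq` the drift dominates and the abundance follows
`df/dt = A(f)/N`, giving the closed-form descent time

$$\tau_{det}(f) = -\frac{1}{r}\left(\log\left|(w-1)f^2+2f-1\right|
  - \Theta(f - f_{eq})\log w\right).$$

The Heaviside argument `f - f_eq` is the only reading that makes
`tau_det(0) = tau_det(1) = 0` and recovers the neutral limit continuously;
the function diverges logarithmically at `f_eq` and evaluation there is an
error by design.

Around `f_eq`, diffusion dominates inside the *tug-of-war region*
`[f_t^-, f_t^+]`, whose boundaries `stochastic_region()` finds by solving

$$|U'(f_t)| = \sqrt{|U''(f_{eq})|/\pi}$$

with bracketed root-finding (`1e-10` in `f`).  The square root on the
right-hand side is a deliberate design choice: equating a first derivative
to a bare second derivative is dimensionally inconsistent and would give
an `N`-independent region, contradicting the diffusive picture; the square
root gives a width `∝ N^{-1/2}` (neutral case: `f_t = 1/2 ±
\sqrt{1/8\pi N}`) and reproduces the `(1/2)log(πN)` growth of the escape
time.

The maximal mean fixation time then decomposes
(`tau_max_approx()`) as

$$\tau_a = \tau_{det}(f_t^\pm) + \tau_{dif}
  \sim \tfrac12\log(\pi N) + \tau_{dif},$$

where `tau_dif` is the `N`-independent cost of diffusing out of the
region.  `estimate_tau_dif()` measures it as the residual of the exact
discrete MFPT at `round(N f_eq)` after subtracting `(1/2)log(πN)`,
averaged over several sizes (default 500–4000), rather than hard-coding a
constant.  Note the convention sensitivity: putting `2πN` inside the
logarithm shifts the residual by `(1/2)log 2 ≈ 0.35`; this package uses
`πN` throughout.  With that convention the measured residual is ≈ 0.41–0.42,
flat in `N` to within ~0.01 and within ~0.15 across `w` — the
`N`-independence, not the third decimal, is the meaningful statement.  For
`w ≠ 1` the two boundary descent times differ; `tau_a` uses their mean,
consistent with the equal probability of escaping either side (they
coincide at `w = 1` by mirror symmetry).

An empirical note on the peak location: the summit of the MFPT curve is
flat on the `N^{-1/2}` scale, so the *argmax* of the discrete MFPT sits
`O(N^{-1/2})` — not `O(1/N)` — from `f_eq` when `w ≠ 1` (measured
offset ≈ `0.25–0.29 N^{-1/2}`).  The tests assert exactly this convergence
rate rather than a tighter one the model does not obey.

## The two-boundary invasion model

An invader inserted at position `x` of a fixated channel (replacing the
native there) forms a contiguous segment `[a, b]`, initially `(x, x)`,
with two inter-species boundaries.  The division rules are unchanged;
summing per-cell rates over the four blocks (natives left of, natives
right of, and the invaders inside the segment, dividing either way) gives
the four segment transitions listed in `invasion_chain()`.  Native
divisions that merely expel other natives are null events and are omitted
from the continuous-time generator — self-loops do not alter first-passage
laws and leaving them out keeps the linear systems well-conditioned.

The transient states are all `1 ≤ a ≤ b ≤ N` *except* `(a, b) = (1, N)`,
which is the FIXED absorbing outcome itself: `N(N+1)/2 - 1` states plus
the two absorbing labels EXTINCT and FIXED.  Absorption probabilities and
the fixation-conditioned times come from sparse backward solves
(`invasion_solve()`, ~5000 unknowns at `N = 100`).  Two structural
identities gate the rate derivation in the tests: a segment touching a
wall reduces exactly to the single-boundary chain, and in the neutral case
the success probabilities over all insertion sites sum to exactly 1 (one
of `N` founder lineages takes over); the whole generator is additionally
checked against a brute-force oracle that applies the microscopic
shift-and-expel rule cell by cell on explicit label vectors.

Edge insertions can never succeed (the wall cell cannot divide inward and
any native push expels it), so their conditional times are undefined and
reported as `NA`.  The success-weighted average conditional time is
non-monotonic in `w`: moderate fitness accelerates successful invasions,
but at very high fitness the occasional deep excursions of a
near-invincible invader slow the conditional average again.

## The cell-level simulator

`simulate_ensemble()` runs the microscopic process itself — label vectors,
fitness-weighted cell choice, linear direction bias, shift-and-expel — in
compiled code, with exponential waiting times at the total event rate
`r (N - 1)` (fitness weights cancel between selection and normalisation).
Null edge divisions are kept in the event stream: they consume time, as
the rate normalisation requires.  The simulator is the stochastic oracle
for every exact solver; conversely the solvers pin down the simulator's
microscopic rules, since the empirical per-event frequencies of boundary
jumps must match `r^±(n)/(r(N-1))` state by state (tested at `N = 10`
with `10^5` single-event probes).

Randomness comes from R's own RNG stream (also inside the compiled loop),
so `set.seed()`/the `seed` argument reproduce ensembles exactly; one
seeded stream is consumed sequentially across replicates.  Ensemble
summaries use a Wilson interval for the win fraction (non-degenerate even
when all replicates agree) and a normal-theory interval for mean times
(`NA` for a single replicate).

What the simulator does *not* emulate: cell geometry and mechanics (sizes,
forces, growth-rate coupling to pressure), position-dependent basal rates,
wall adhesion, sub- or super-linear direction bias, and multi-lane 2D
channels.  Agreement between simulator and solvers therefore validates the
lattice abstraction's internal consistency, not those physical effects.

## Defaults, problem sizes and tolerances

* `r = 1` (one generation per time unit), `w = 1` unless varied.
* Quadrature/BVP meshes as above; root-finding tolerance `1e-10` in `f`.
* Exact-solver cross-checks at `1e-10`; closed-form Moran checks `1e-8`.
* Test and verification sizes: exact chains up to `N = 6400` (tridiagonal),
  invasion chains up to `N = 200` (~20k states), ensembles of `10^5`
  replicates at `N = 20`, chosen so each property is measured where its
  asymptotic behaviour is already clean.

## Known limitations

* The `(1/2)log(πN) + tau_dif` decomposition is heuristic; the additive
  constant depends on the `πN` vs `2πN` convention as described above, and
  no rigorous error bound is provided for `tau_a` (empirically within 10%
  of the exact maximum at `N = 1000`).
* The continuum MFPT solver is not intended for `N` beyond ~2000 (mesh
  cap); use the exact discrete solver there.
* Conditional-time comparisons across fitness values flip sign below the
  balance point (conditioning on rare success selects fast paths); claims
  about "faster fixation of the fitter species" hold for starts at or
  above it.
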