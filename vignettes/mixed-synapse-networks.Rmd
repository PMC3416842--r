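---
title: "Mixed-synapse attractor networks: model, mean-field theory, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-synapse attractor networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixnet)
```

## The model

The network consists of $N$ binary neurons $\sigma_i = \pm 1$, updated
*synchronously*: all spins are redrawn simultaneously from their local
fields $h_i = \sum_j J_{ij}\sigma_j(t) + \theta_i$ with the parallel Glauber
(Little-model) rule

$$P\{\sigma_i(t+1) = \pm 1\} = \frac{e^{\pm\beta h_i}}{2\cosh \beta h_i}
  = \tfrac12\bigl(1 \pm \tanh \beta h_i\bigr),
  \qquad \beta = 1/T ,$$

independently across neurons.  At $T = 0$ this is the deterministic map
$\sigma_i(t+1) = \mathrm{sign}(h_i)$, with the tie-break
$\mathrm{sign}(0) \equiv +1$ fixed for reproducibility (ties are
measure-zero for generic patterns but do occur in small hand-built
examples).

The synaptic matrix is a mixture of a symmetric and an asymmetric Hebbian
part,

$$J = \nu\,\Xi^{s} + (1-\nu)\,\Xi^{a}, \qquad
  \Xi^{s}_{ij} = \frac1N \sum_{\mu=1}^{P} \xi^{\mu}_i \xi^{\mu}_j, \qquad
  \Xi^{a}_{ij} = \frac1N \sum_{\mu=1}^{P} \tilde\xi^{\mu+1}_i
  \tilde\xi^{\mu}_j ,$$

with the sequence index taken modulo $P$ and zero self-couplings
($J_{ii}=0$, the standard convention for Hopfield-class models).  The
symmetric part stores its patterns as independent fixed points (associative
memory, AM); the asymmetric part stores an ordered sequence as a single
cyclic attractor traversed one pattern per update (sequential pattern
recognition, SPR).  Two constructions are supported:

* **one-set** — the same patterns feed both parts
  ($\tilde\xi^\mu = \xi^\mu$), putting the two retrieval modes in direct
  competition on the same material;
* **two-set** — two independent random sets feed the two parts, so a
  pattern can be a fixed point while a different pattern participates in a
  cycle.

Retrieval quality is measured by the overlap
$m = N^{-1}\sum_i \sigma_i \xi_i \in [-1, 1]$; a state with overlap $m$ has
a fraction $(1+m)/2$ of its neurons correct, so $m = 0.5$ means 75%
correct — the boundary we use between "weak" and unusable retrieval.  The
load is $\alpha = P/N$ for a fully connected network.  When the matrix is
diluted to in-degree $K$ (each neuron keeps exactly $K$ randomly chosen
inputs, fixed for the run, and kept weights are rescaled by $N/K$ so field
magnitudes are preserved in expectation), the effective load becomes
$P/K$.  The rescaling is a package choice: it keeps the fully connected
mean-field theory approximately valid for the diluted simulator, and it can
be disabled (`dilute(..., rescale = FALSE)`).

## Stationary mean-field equations

Near saturation ($\alpha$ fixed as $N \to \infty$) one pattern is assumed
condensed at each time; all others contribute quenched Gaussian
interference.  The stationary state of each of the four
(dynamics $\times$ construction) combinations is described by three order
parameters: the condensed overlap $m$, the interference variance $r$
(scaled so the condensed field noise is $z\sqrt{\alpha r}$, $z \sim
N(0,1)$), and the persistent state correlation $C$, with single-site
susceptibility $\chi = \beta(1 - C)$.  The package derives the closures by
a signal-to-noise / linear-response analysis of the synchronous dynamics;
the resulting self-consistency system is

$$m = \Bigl\langle\!\Bigl\langle \tanh \beta h \Bigr\rangle\!\Bigr\rangle,
  \qquad C = \Bigl\langle\!\Bigl\langle \tanh^2 \beta h
  \Bigr\rangle\!\Bigr\rangle, \qquad
  h = a\,m + s\,b\,m + z\sqrt{\alpha r},$$

where $\langle\langle\cdot\rangle\rangle$ averages over $z$ and over the
binary sign $s = \pm 1$.  The signal weight is $a = \nu$ for AM and
$a = 1-\nu$ for SPR.  The *drag* weight $b$ is nonzero only in the one-set
model, where the condensed pattern itself generates a macroscopic field
along its neighbour in the sequence: $b = 1-\nu$ for AM (the asymmetric
part pushes a fixed point toward its successor) and $b = \nu$ for SPR (the
symmetric part drags the cycle back toward the current pattern).  Because
the condensed pattern and its neighbour are independent random $\pm 1$
vectors, the drag acts site-wise as a binary random field of magnitude
$b\,m$.

The interference closes as $r = C\,S(\chi)$.  Two accumulation mechanisms
occur.  In a *frozen* (fixed-point) state the interference from the pattern
set that shapes the state adds **coherently** across time, giving factors
$(1 - g\chi)^{-2}$; in a *cycling* state the signs refresh every step and
the variances add **incoherently**, giving $(1 - g^2\chi^2)^{-1}$:

| system | $S(\chi)$ |
|---|---|
| one-set AM | $\bigl[(1-\nu\chi)^2 - (1-\nu)^2\chi^2\bigr]^{-1}$ |
| one-set SPR | $\bigl[1 - (\nu^2 + (1-\nu)^2)\chi^2\bigr]^{-1}$ |
| two-set AM | $\nu^2(1-\nu\chi)^{-2} + (1-\nu)^2\bigl(1-(1-\nu)^2\chi^2\bigr)^{-1}$ |
| two-set SPR | $\nu^2(1-\nu^2\chi^2)^{-1} + (1-\nu)^2\bigl(1-(1-\nu)^2\chi^2\bigr)^{-1}$ |

In the one-set systems the interference travels along one chained pattern
sequence; equal-time cross-covariances between neighbouring chain overlaps
are dropped (a diagonal closure).  The all-zero point is an exact fixed
point of every system.  Consistency anchors, each computed by the test
suite rather than assumed: at $\nu = 1$ the AM systems reduce to the
classical symmetric (Hopfield/Little) equations with zero-temperature
capacity $\alpha_c \approx 0.1379$ and spin-glass line
$T_{sg} = 1 + \sqrt{\alpha}$; at $\nu = 0$ both SPR systems reduce to the
asymmetric sequence-processing model with $\alpha_c \approx 0.2691$; the
one-set and two-set systems coincide identically at these pure limits.

### Spin-glass solutions and transition temperatures

Setting $m = 0$ closes the system in $C$ alone.  Expanding around the
trivial solution, spin-glass order appears when
$\alpha\beta^2 S(\beta) = 1$.  For the one-set systems this is closed-form:

$$T_{sg}^{AM} = \nu + \sqrt{\alpha + (1-\nu)^2}, \qquad
  T_{sg}^{SPR} = \sqrt{\alpha + \nu^2 + (1-\nu)^2};$$

for the two-set systems the same condition is solved by bracketed
root-finding (it is a polynomial condition in $T$ with a unique root above
$\max(\nu, 1-\nu)$).  All four are finite and positive for every
$\alpha > 0$ and $\nu \in [0,1]$, and the test suite verifies each against
a numerically linearized stationary map to $10^{-6}$.

### Zero temperature

The $\beta \to \infty$ limit is a separate code path (the finite-$T$
integrands degenerate): with $C \to 1$ and $x = m/\sqrt{2\alpha r}$ the
system reduces to $m = \langle \mathrm{erf}\rangle$-type equations with an
explicit susceptibility, and the whole retrieval branch collapses onto a
one-parameter family $\alpha(x)$ (`zero_t_load_family()`).  Nontrivial
solutions exist iff $\alpha \le \max_x \alpha(x)$; the maximum is the
storage capacity, located by a dense scan plus golden-section refinement.

## Numerical choices

* **Gaussian averages.**  `gauss_expectation()` uses fixed-order
  Gauss–Hermite quadrature (order 120; fixed rather than adaptive so that
  solver outputs are smooth in $\alpha$, $T$, $\nu$ — bisection on solution
  existence needs noise-free continuity).  Inside the stationary map the
  $\tanh/\tanh^2$ moments switch representation when the integrand becomes
  kink-like (when $\beta\sqrt{\alpha r} > 1$): the moment is then computed
  as its $T = 0$ erf/sign part plus a correction integral localized at the
  kink, evaluated with a fixed 200-point Gauss–Legendre rule.  The two
  regimes agree to $\sim 10^{-12}$ at the switch, so the map stays smooth
  and accurate down to $T = 10^{-3}$ and below.
* **Branch solving.**  The retrieval branch is solved by damped fixed-point
  iteration (damping 0.5, tolerance $10^{-10}$, cap $10^4$ iterations, all
  config-exposed) from the fully condensed initialization $m = C = 1$;
  "existence" means convergence with $m > 0.01$.  Iterates are kept inside
  the validity domain of $S$ by flooring $C$ at
  $1 - 0.999\,\chi_{max}/\beta$; the floor is provably inactive wherever
  the trivial solution is stable, so it cannot mask a collapse.  The
  spin-glass branch is solved by bracketed root-finding on its scalar
  $C$-equation, because at low temperature the damped iteration develops a
  stable flip-flop around the solution (the map slope in $C$ passes below
  $-1$).
* **Critical loads.**  `critical_alpha()` bisects on retrieval-branch
  existence to $10^{-4}$ in $\alpha$ and reports bracket failure loudly
  (the error path is exercised in the tests at temperatures above every
  retrieval region).
* **Region labels.**  HC requires $|m| \ge \theta_{HC} = 0.9$ (anti-pattern
  retrieval counts: specular copies are retrieved states); WC — which the
  theory produces only in the one-set AM system — requires
  $0 < |m| < \theta_{WC} = 0.5$, the value pinned by the 75%-correct
  argument above; overlaps in $[0.5, 0.9)$ are reported as an explicit
  indeterminate band rather than silently binned; SG/TS label the remaining
  cells by whether spin-glass order survives.  Both thresholds are
  arguments, not constants.

## Simulation protocols

The AM protocol corrupts each stored pattern by an exact 10% of spin flips
(an exact count rather than per-entry Bernoulli, so the initial overlap is
deterministically 0.8 and protocol tests are exact), evolves 35 synchronous
steps, and averages the final overlaps.  The SPR protocol corrupts one
sequence pattern, evolves $3P$ transient steps (three periods of the
supposed cycle), aligns the cycle phase to the best-matching pattern at the
first post-transient step — the stored order fixes relative phase only, so
an alignment convention is needed — and then averages the signed overlap
against the sequence advanced in order over one further period.  Signed
(not absolute) overlap is reported throughout; anti-cycle retrieval shows
up as $m \approx -1$ and is not folded in silently.

Randomness is managed by one master seed per run from which independent
child streams are derived (`derive_seeds()`) for pattern generation,
corruption, dilution masks and thermal noise; every output table records
the master seed, and the zero-temperature attractor detector
(`detect_attractor()`) is exact (state hashing until recurrence).

### What the synthetic generator emulates — and what it does not

`generate_random_patterns()` reproduces the theory's own ensemble:
independent equiprobable $\pm 1$ entries, hence pairwise overlaps of
$O(N^{-1/2})$.  `glyph_fixture()` emulates storing digitized grayscale
glyph images (procedurally drawn seven-segment digits over a noisy gray
background, each pixel encoded as 8 spins, most-significant bit first, bit
1 $\to$ +1), giving high-dimensional, near-orthogonal binary patterns with
recognizable decoded bitmaps — the statistical role of stored images,
without bundling image assets.  Real images are *correlated* bit strings;
the mean-field theory assumes uncorrelated patterns, and passing tests on
these fixtures says nothing about strongly correlated pattern sets.
Likewise the simulator's dilution draws connections uniformly; structured
topologies are out of scope.

### Study conditions

The simulation defaults mirror the glyph-image experiment at reduced size:
$N = 2000$ neurons, in-degree $K = 500$, $10 + 10$ patterns, 10% initial
corruption, 35-step AM transient, $3P$-step SPR transient.  Mean-field
acceptance checks use: $101 \times 101$ $(\nu, \alpha)$ grids at $T = 0$
(where the reduced equations make the full grid cheap), $41 \times 41$ and
$17 \times 13$ grids at finite temperature, a capacity cross-check
simulation at $N = 4000$, and 10-seed spot checks at $N = 2000$.  These
sizes were chosen so the complete suite documents the same phenomenology as
the full-size experiment while remaining convenient to run routinely.

## Findings specific to this implementation, and limitations

* **Coexistence.**  At $T = 0$ (and at $T = 0.1, 0.2$) the two-set model
  has a non-empty intersection of the AM-HC and SPR-HC regions over a broad
  $\nu$ interval, while the one-set model's intersection is empty on the
  full grid — AM-HC requires $\nu > 1/2$ and SPR-HC $\nu < 1/2$, meeting
  only at the frustrated boundary $\nu = 1/2$ where the retrieval overlap
  is pinned at $1/2$.
* **Mirror symmetry is approximate.**  The two-set AM system at $\nu$ and
  SPR system at $1-\nu$ have identical signal structure but different
  own-set interference (coherent vs incoherent), so their critical lines
  mirror only qualitatively; at $T = 0.1$ the lines differ by up to
  $\approx 0.14$ in $\alpha$, consistent with the unequal endpoint
  capacities ($0.138$ vs $0.269$).  The acceptance test asserts strict
  mirror equality and is expected to fail; the discrepancy is reported, not
  hidden.
* **Transition character.**  In this closure the one-set AM retrieval
  branch always disappears discontinuously (a saddle-node, or a
  susceptibility runaway in which the weakly pinned half of the neurons
  pushes $\chi$ into the coherent singularity).  A continuous
  HC$\to$WC$\to$TS decay of $m$ is not attainable: the small-$m$
  bifurcation condition $\nu\chi = 1$ cannot be met on the closure's
  validity domain $\chi < 1$.  A continuous, weakly correlated retrieval
  branch does exist for $\nu < 1/2$ (reentrant in $T$, $m < 0.5$
  throughout).  One-set SPR retrieval never enters the WC band ($m$ stays
  above $0.5$ wherever the branch exists, dipping to $\approx 0.7$ near the
  critical line before jumping to zero).
* **Replica-symmetric level.**  The closures are at the level of a single
  condensed pattern with Gaussian interference and linear response; no
  replica-symmetry-breaking corrections, no stability (AT-line) analysis,
  no quasi-periodic or partially-shared-set variants.
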