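---
title: "Replica-exchange umbrella sampling binding free energies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replica-exchange umbrella sampling binding free energies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reusbind)
```

# The problem

Absolute binding free energies of host–guest complexes — for example the
cucurbit[8]uril (CB[8]) host with small drug-like guests used in blind
prediction challenges — are a standard stress test for free-energy methods.
One established route is a potential-of-mean-force (PMF) calculation: the
guest is pulled along a geometric reaction coordinate through the host,
umbrella sampling with replica exchange (REUS) recovers the free-energy
profile along that coordinate, and a set of analytic correction terms turns
the profile into a standard-state binding free energy.

`reusbind` implements that entire workflow, end to end, on a toy model whose
exact answers are available in closed form or by quadrature.  Everything
downstream of the molecular-dynamics engine — the umbrella ladder, the
Metropolis exchange criterion, WHAM reweighting, the standard-state and
restraint corrections, stereoisomer averaging, the protonation-state
thermodynamic cycle, and the benchmark statistics — is the production
algorithm; only the force field is replaced by a separable model potential.
That design lets every stochastic stage be validated against exact
statistical mechanics, which is impossible on a solvated atomistic system.

# The toy system

A single guest-sized particle (default 100 amu) moves in the separable
potential

$$U(z, r) \;=\; -D\, e^{-z^2 / 2w^2} \;+\; a\,r^2 ,$$

with soft harmonic walls outside the axial range.  The axial coordinate $z$
*is* the reaction coordinate $\zeta$ (the signed projection of the guest COM
onto the host axis), the Gaussian well of depth $D$ at $z=0$ is the bound
pose, and the flat region on either side is the unbound plateau — the shape
a symmetric host produces in a bidirectional pull.  Separability makes the
marginal PMF along $\zeta$ equal to the axial potential up to a constant, so
`analytic_pmf()` is exact.

Defaults, chosen once as a realistic stand-in and then frozen:

| parameter | default | why |
|---|---|---|
| `well_depth` | 5 kcal/mol | mid-range host–guest affinity; deep enough for a well-separated bound state, shallow enough that both basins are sampled |
| `well_width` | 1.5 Å | bound-pose fluctuations of a few tenths of an Å at 298 K, like a guest in a rigid macrocycle |
| `axial_range` | −13..14 Å | the span of the reference pulling protocol |
| `radial_stiffness` | 0.3 kcal/mol/Å² | lateral excursions of a few Å, comfortably inside the 7.5 Å cylinder |
| `temperature` | 298.15 K | experimental buffer temperature |
| friction | 1 ps⁻¹ | the Langevin thermostat setting of the reference protocol |
| `wall_stiffness` | 10 kcal/mol/Å² | confines the coordinate to its range without hard reflections |

The propagator is BAOAB-split Langevin dynamics with an exact
Ornstein–Uhlenbeck friction substep, `dt = 0.002` ps.  At the stiffest
curvature in the default system ($\omega\,dt < 0.02$) the discretisation
error in sampled configurations is far below every tolerance used in the
tests.  A non-finite coordinate aborts the run with an explicit "time step
too large" error rather than propagating NaNs.

Two oracles accompany the sampler: `sample_biased_exact()` draws i.i.d.
reaction-coordinate values from the exact biased marginal by inverse-CDF on
a 4096-point grid (linear interpolation between grid points), and
`generate_unbound_positions()` produces uniform annular-cylinder fixtures on
which the effective-volume formula is exact.

# Umbrella ladder and restraints

The umbrella bias is the no-half-factor harmonic
$V_m(\zeta) = k_m(\zeta - d_m)^2$ (the CHARMM convention — all stiffnesses
in this package are interpreted accordingly).  The default ladder follows
the reference protocol: 32 windows from −13 to 14 Å with a densified bound
region, realised as fixed 0.5 Å spacing inside [−3, 3] and the remaining
windows spread uniformly over the two flanks in proportion to flank length,
endpoints pinned to the span.

The uniform window stiffness is the one genuinely free knob, and it was
calibrated — as the protocol prescribes — to the observed 20–30% neighbour
exchange rate.  For two harmonic windows spaced $s$ on a flat landscape the
mean Metropolis acceptance is $2\Phi(-s\sqrt{\beta k})$; with the ladder's
1.1 Å flank spacing this brackets the target band between $k = 1$ and
$k = 1.5$ kcal/mol/Å², and a single measurement of the candidates fixed
**k = 1.25 kcal/mol/Å²** (mean acceptance ≈ 0.27). The value was frozen
before the downstream analyses were built.

The cylindrical restraint is flat-bottomed: zero inside radius 7.5 Å of the
host axis, $5\,(\rho - 7.5)^2$ kcal/mol outside.  A restraint meant only to
*keep* the guest inside the host's cylinder should exert no interior force,
and because it depends only on the lateral coordinate it is constant along
$\zeta$ and drops out of the WHAM reweighting.

Initial configurations come from a steered pull: a moving harmonic
restraint (5 kcal/mol/Å²) dragged linearly across the full span; each
window takes the recorded snapshot nearest its center.

# REUS

Each cycle alternates a dynamics segment (default 20 steps, the toy
analogue of the 2 ps attempt interval) with one exchange sweep.  Sweeps
alternate even/odd neighbour pairs, one attempt per pair per sweep — the
standard deterministic-alternation scheme, which satisfies balance because
the pair choice is independent of the state.  The exchange exponent is

$$\Delta = \beta\left(V_m(\zeta_j) - V_m(\zeta_i) - V_{m+1}(\zeta_j) +
V_{m+1}(\zeta_i)\right),$$

accepted with probability $\min(1, e^{-\Delta})$.  An accepted exchange
swaps the *window labels* between the two replicas; since the umbrella
potentials are momentum-independent, velocities are untouched, and the
label permutation remains a bijection at all times.  One reaction-coordinate
sample per window is recorded at the end of every cycle, already sorted by
window label; the default production length is 20,000 cycles per window,
the package's toy-scale stand-in for 10–20 ns per replica.

# WHAM

Window histograms share one set of bin edges (default width 0.2 Å) and the
umbrella bias is tabulated at bin centers (classic midpoint-rule WHAM,
adequate at this bin width relative to every tolerance used).  The
self-consistent equations

$$p_b \propto \frac{\sum_m n_{mb}}{\sum_m N_m\, e^{\beta f_m - \beta
V_m(\zeta_b)}}, \qquad f_m = -\tfrac{1}{\beta} \ln \sum_b p_b\, e^{-\beta
V_m(\zeta_b)}$$

are iterated (in compiled code) until the window free energies move by less
than 1e-7 kcal/mol, with the gauge fixed by $f_1 = 0$ and a hard error on
non-convergence or on a disconnected window-overlap graph.  An independent
route to the same solution — direct L-BFGS minimisation of the WHAM profile
likelihood with analytic gradient (`wham_mle()`) — is kept as a
cross-check; the two agree to better than 1e-6 kcal/mol in the tests.

The PMF is $-k_BT \ln p_b$, anchored so its minimum over populated bins is
zero; empty bins are `NA`, never interpolated.

Two conventions are provided for reading the pulling free energy
$\Delta G^{\mathrm{REUS}}$ off the profile, because the choice is genuinely
open: `"depth"` (free energy at the bound minimum minus the mean over the
unbound plateau — what one reads off a published profile figure) and
`"integrated"` ($-\tfrac{1}{\beta}\ln[\langle e^{-\beta F}\rangle_{bound} /
\langle e^{-\beta F}\rangle_{unbound}]$).  The integrated form is the one
that composes exactly with the correction terms, so it is the pipeline
default and the one validated against quadrature; neither is asserted to be
"the" published convention.  The bound region defaults to the densified
[−3, 3] Å; the unbound reference is the outermost 3 Å of each flank
(bidirectional) or of the single flank (unidirectional).

Uncertainties come from a moving-block bootstrap over each window's series
(default 50 blocks of 50 cycles, chosen to exceed the measured
reaction-coordinate autocorrelation time within a window), rerunning the
full histogram → WHAM → $\Delta G$ chain per replicate.

# Correction terms

**Standard-state (rest-off).**  $\Delta G^{\mathrm{rest-off}} = -k_BT
\ln(V_0/V_{\mathrm{eff}})$ with $V_{\mathrm{eff}} = \pi(r_{\max}^2 -
r_{\min}^2)\,h_{\max}$ taken from the radial and axial extrema of the COM in
the first (unbound) replica.  Extrema are used exactly as defined even
though they are noise-sensitive; a percentile variant (`trim`) exists but is
off by default.  $V_0$ is fixed at 1649.76 Å³ — the value the reference
protocol states for the 1 M standard state — rather than the textbook
1660.5 Å³, and is overridable.

**Restraint-on (TI).**  The cost of switching on the bound-pose
reaction-coordinate restraint is computed by thermodynamic integration with
linear coupling $V(\lambda) = \lambda V_{\mathrm{restraint}}$, so the
integrand is $\langle V_{\mathrm{restraint}}\rangle_\lambda$; trapezoidal
quadrature over the (non-uniform) 10-point schedule
$\lambda = 1, 0.95, \ldots, 0.1, 0$, averaged over 5 bound poses taken at
evenly spaced times from the bound window (the selection rule for the
reference protocol's "5 chosen binding poses" is unstated; even time spacing
is the neutral choice).  Per-pose toy lengths are 2,000 equilibration +
10,000 production steps per $\lambda$, standing in for the 100/200 ps NVT
runs.

A caution documented here because the tests exercise it: with linear
coupling the integrand behaves like $k_BT/2\lambda$ whenever the *uncoupled*
ensemble is much wider than the restraint, so on a flat domain the sparse
production grid near $\lambda = 0$ overestimates the integral.  In the bound
pose — the term's actual use — the uncoupled ensemble is already confined by
the binding well, the integrand is smooth, and the default grid is accurate
(the tests verify grid-refinement invariance there).  The closed-form
validation on a flat 10 Å domain therefore uses a geometrically refined
$\lambda$ grid near zero.

**Assembly and sign convention.**  The binding free energy is assembled as
the plain sum

$$\Delta G^{\mathrm{bind}} = \Delta G^{\mathrm{REUS}} + \Delta
G^{\mathrm{rest-off}} + \Delta G^{\mathrm{rest-on}},$$

the convention under which the reference per-guest component tabulation is
internally consistent row by row.  The alternative bookkeeping that negates
all three components describes the reverse (unbinding) direction; the two
conventions circulate in the literature and the tabulated one is taken as
authoritative here.  A consequence worth stating plainly: this assembled
number is a bookkeeping composition, not the literal
$-k_BT\ln(Z_{\mathrm{site}}/V_0)$ binding constant, so the package's
end-to-end validation compares it against the *identically composed*
quadrature reference (`toy_binding_oracle()`): integrated-mode pulling free
energy on the analytic PMF, the cylinder-shell volume formula on the
measured unbound extrema (the formula itself is validated separately on
uniform fixtures with known extrema), and the exact restraint-on free-energy
difference that linear-coupling TI equals.  Every stochastic stage —
sampling, exchange, WHAM, TI — is thereby checked against exact statistical
mechanics with no shared code between route and reference.

**Stereoisomer averaging.**  R/S binding free energies are averaged
arithmetically; the reported uncertainty is the RMS of the two component
uncertainties, $\sqrt{(\sigma_R^2+\sigma_S^2)/2}$ — the convention the
reference tabulation's printed error bars actually follow (a strict
standard-error-of-the-mean propagation would give values ~30% smaller than
those printed).

# Protonation-state correction

For a guest whose pKa (7.5) straddles the experimental pH (7.4), the bound
and free protonation equilibria form a thermodynamic cycle:

$$pK_a^{\mathrm{Bound}} = pK_a^{\mathrm{Free}} + \frac{\beta}{\ln 10}
\left(\Delta A^{L} - \Delta A^{HL^+}\right), \qquad
\Delta G^{pH} = \Delta G^{HL^+} - k_BT \ln \frac{1 + 10^{\,pH -
pK_a^{\mathrm{Bound}}}}{1 + 10^{\,pH - pK_a^{\mathrm{Free}}}} .$$

Two notational ambiguities were resolved numerically: the direction of the
$\Delta\Delta A$ gap is neutral-minus-protonated, and the "log" under the
$1/\beta$ prefactor is the natural log — with these choices the published
pH-corrected entries for two of the three parameter sets reproduce to
0.01 kcal/mol (the third differs by ~0.04, evidently computed upstream from
unrounded inputs).  The population factor is evaluated with an
overflow-guarded log-sum, and the cycle closes exactly when entered from the
neutral leg instead.  Note the corrected value is non-*decreasing* in the
bound-state pKa at fixed protonated affinity — a higher bound pKa only
removes the free-energy gain of deprotonating the complex.

# Benchmark statistics

RMSE uses the population denominator $n$; Kendall's rank correlation is
tau-a, $(C-D)/\binom{n}{2}$, with ties rejected rather than silently
corrected; the mean signed error is reported as experiment minus
calculation.  Each convention was fixed by checking which one reproduces the
published statistics table from the published binding table (RMSE 4.68,
$r$ 0.40, $\tau$ 0.33 for the first parameter set, and the rank correlations
of the other two).  Two printed entries are not reproducible under any
convention tried — the first parameter set's MAE/ME pair violates
$|ME| \le MAE$ as printed — and the recomputation report
(`reproduce_published_tables()`) flags rather than chases them.

# The unidirectional variant

A unidirectional pull is configured by truncating the ladder at the bound
center and using the remaining (left) flank as the unbound reference.
Because both $\Delta G$ conventions normalise per unit length of the regions
they average over, a symmetric profile gives the same answer from one flank
as from two; the package's paired runs agree to well under 0.5 kcal/mol,
mirroring the agreement the full-scale protocol reports.

# What the toy validates — and what it cannot

The generator emulates: a single dominant binding pose on a symmetric
host's axis, harmonic lateral confinement, Langevin kinetics at 298.15 K,
umbrella biases and a flat-bottom cylinder identical in form to the
production protocol, and realistic exchange statistics.  It does not
emulate: solvent and its relaxation timescales, guest conformational
degrees of freedom (the slow orthogonal coordinates that make real REUS
convergence hard), multiple binding poses, asymmetric profiles from
incomplete mixing, or force-field error.  Passing tests therefore certify
the *estimators* — that WHAM, the exchange criterion, TI, the corrections
and the statistics are implemented correctly and compose consistently —
not that any particular atomistic simulation is converged.

Problem sizes used throughout (20,000 cycles × 32 windows, 20,000
samples/window for the WHAM recovery check, 50 bootstrap replicates, 5 TI
poses × 16 λ points) were chosen so the full validation completes in about
a minute on one core while leaving every tolerance limited by statistics,
not by the budget.

# Known limitations

* Classic binned WHAM only; no MBAR/per-sample reweighting, no 2-D PMFs.
* The effective-volume estimator inherits the extrema convention's
  sensitivity to run length; the bootstrap captures its variance but not
  its slow logarithmic drift with sample size.
* Block length is fixed by configuration, not estimated from the data; a
  badly mis-set block would bias the reported uncertainties.
* The exchange log stores window-pair swaps, so replica traces are
  reconstructed by replay (`replica_trace()`), which assumes the log is
  complete and ordered.
* The toy guest is a point particle; the COM reaction-coordinate machinery
  (`compute_reaction_coordinate()`) is exercised against brute-force
  oracles but not used by the toy propagator itself.
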