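---
title: "Models and methods in kaikinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kaikinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaikinetics)
```

# The kinetic model

The cyanobacterial clock protein KaiC autophosphorylates on two CII-domain
sites. Each subunit is tracked by three properties: its phosphoform (U
unphosphorylated, T phospho-Thr432, S phospho-Ser431, D doubly
phosphorylated), the nucleotide in its CII pocket (ATP, "TP", or ADP,
"DP"), and whether a KaiA dimer is bound. That gives the 16 states of
`kai_states()`, connected by four reaction classes:

* **Phosphotransfer** `C_TP_X <-> C_DP_Y` for the pairs (U,T), (U,S),
  (T,D), (S,D). Phosphotransfer moves a phosphate between a protein site
  and the bound nucleotide, so an ATP-bound subunit can only
  phosphorylate and an ADP-bound subunit can only dephosphorylate, and
  every transfer flips the nucleotide state.
* **Hydrolysis** `C_TP_X -> C_DP_X + Pi`, irreversible. This is the only
  route into ADP-bound states in the absence of KaiA and is what makes
  sustained dephosphorylation possible.
* **KaiA binding/unbinding** on every state, with the KaiA dimer
  concentration (total monomer / 2) entering the on-flux. Free KaiA is
  eliminated algebraically by conservation rather than integrated as a
  state, so KaiA mass is conserved exactly.
* **Nucleotide exchange**, KaiA-catalyzed only, on ADP-bound KaiA-bound
  states: `AC_DP_X -> AC_TP_X` at `krDP * pctATP/100`. The linear %ATP
  factor comes from a quasi-steady-state treatment of the transiently
  empty pocket with equal ATP/ADP on-rates; ATP release is neglected, so
  there is no reverse exchange. This is the single step through which
  both [KaiA] and the metabolic signal %ATP act.

Rates are parameterized multiplicatively: six base rate constants (`kp`,
`kd`, `ka`, `kb`, `krDP`, `kh`) and log10 state-dependence factors
(Delta-k). Reactions without a listed factor run at the bare base rate;
the U<->T pair without KaiA anchors the phosphotransfer pair, ATP-bound U
anchors KaiA on/off, and the U phosphoform anchors hydrolysis and
exchange. 38 factors exist; detailed balance (below) leaves 34 free.
With the global error variance and 7 free initial fractions the model has
48 free scalars.

## Detailed balance

Every reversible four-state cycle (two phosphotransfer-linked KaiA-free
states plus their KaiA-bound counterparts) must have zero free-energy
change: the product of forward rate constants around the cycle equals the
product of reverse ones. The four cycles each fix one KaiA-on factor (the
T and S on-rates, both nucleotide forms); `kai_detailed_balance()` solves
the constraints in log10 space and `kai_params()` applies them at
construction, so an invalid set cannot be built. The unit tests verify
the constraint the way a referee would: by multiplying the actual
per-reaction rates around each cycle and checking the forward/reverse
ratio is 1 to 1e-12 for randomized parameter sets. (The bilinear KaiA
binding step appears once in each direction of a cycle, so the free-KaiA
concentration cancels and the constraint involves rate constants only.)

## Numerics

Internal rates are s^-1 (`ka` in s^-1 uM^-1); the time axis is hours, with
the 3600 conversion applied once inside the integrator boundary. The stiff
system is integrated with a BDF method (deSolve; rtol 1e-6, atol 1e-9 uM)
through a derivative function compiled from C -- the right-hand side is
`dx/dt = 3600 (M0 + A_free Mb) x` for two precomputed 16x16 operators,
plus a cumulative inorganic-phosphate state tracking hydrolysis flux.
Integration failure is reported as `NULL` and treated as log-posterior
-Inf by all callers. Concentrations in `[-atol, 0)` are clamped to zero
for observables only, never fed back into the state. A four-state
U-phosphoform subnetwork with KaiA clamped in excess is linear, and the
test suite holds the integrator to the matrix-exponential solution of that
subnetwork at 1e-8.

# Priors, likelihood, posterior

Base rates carry log10-normal priors (sd 3), centered at zero except the
measured KaiA on/off rates (`ka` = 0.0279 s^-1 uM^-1, `kb` = 0.0663
s^-1). Every Delta-k carries a log10-Laplace prior with scale b = 1 -- an
l1 penalty that pulls each state-dependent rate toward its base rate
unless the data say otherwise; the KaiA off-rate factors are centered so
the prior mode reproduces the measured per-phosphoform dwell times
(tau_T = 1.0 s, tau_S = 0.43 s, tau_D = 0.26 s), applied to both
nucleotide forms. The error variance gets Inv-Gamma(1, 0.01) uM^2 and is
sampled as an ordinary coordinate rather than marginalized. The eight
initial fractions get a Dirichlet prior with concentration
(20, 100, 1, 1, 1, 1, 1, 1) -- most KaiC starts in ADP-bound U, the
endpoint of autodephosphorylation -- evaluated on all eight fractions
reconstructed from the seven free ones.

The likelihood is Gaussian with a single global sigma for all
(de)phosphorylation records. Observations are percentages while the
variance prior is in uM^2, so sigma is converted through the total KaiC
concentration (`sigma_pct = sqrt(sigma2) * 100 / kaiC_uM`); this
convention is fixed here and covered by tests. Dephosphorylation records
are weighted 4x (the full per-record log density, normalization included
-- the choice the weighting convention leaves open) to balance the much
larger phosphorylation design. The hydrolysis constraint is an upper
bound, not a measurement, so it enters as a half-harmonic: zero below the
bound, `-(ADP_model - ADP_exp)^2 / (2 sigma_h^2)` above it, continuous
and once-differentiable at the junction. The bound (29.8 ADP per KaiC per
day) and its width (5.1, the only uncertainty figure available) are
converted to uM over the 12 h window; the model-side quantity is
cumulative Pi production plus all ADP-bound KaiC at 12 h.

# Sampling and fitting

`kai_run_ensemble()` implements the affine-invariant stretch move:
walker k moves to `theta_j + z (theta_k - theta_j)` against a partner j
drawn from the rest of the ensemble, accepted with probability
`min(1, z^(N-1) exp(dlogpost))`. The stretch factor density is g(z)
proportional to 1/sqrt(z) on [1/alpha, alpha] -- the form for which the
z^(N-1) acceptance factor is exact; a 1/z variant is available behind
`variant = "reciprocal"` for comparison, since both forms circulate in
the literature and they differ only in the step-length distribution.
Updates are sequential over walkers; all randomness flows through R's
RNG, so seeded runs reproduce bit-for-bit. Tempering raises only the
likelihood to beta, never the prior.

`kai_fit()` wraps the sampler in a four-step heuristic: (1) draw the
ensemble from the prior and anneal up a beta ladder (default 0.3 to 1.0
in steps of 0.1, 20,000 sweeps each at full scale); (2) rank all pooled
samples, de-duplicate, take the top 300 and pick 10 by stratified rank
(the best plus nine spread evenly -- the selection rule the procedure
leaves open), then polish each with Powell's method; (3) reseed the
ensemble around the optima with Gaussian jitter (sd 0.001, which also
keeps the stretch proposal valid for coincident walkers), allocating
walkers proportionally to posterior^0.6 so weaker optima keep scouts,
with the best optimum always retained exactly; (4) sample, and terminate
after an extra run when sampling stops discovering maxima more than 1.0
nat above the optimized values (the improvement threshold is a
configurable operationalization of "no new local maxima"). The `"paper"`
profile of `kai_config()` carries the full-scale constants; the `"test"`
profile keeps the structure with all chain lengths cut by >= 50x.

Powell's direction-set method is implemented in-package
(`kai_powell()`): sequential Brent line minimizations along a direction
set, replacing the direction of largest decrease with the net sweep
displacement, without maintaining strict conjugacy. No installed R
package provides Powell's method; the implementation is cross-checked
against Nelder-Mead in the tests.

# Evidence and model comparison

`kai_log_evidence()` estimates the log marginal likelihood by a
free-energy-perturbation ladder over tempered targets
`q_lambda = L^lambda * prior`. Each sampled stage estimates the
increment to the next-lower lambda from its own samples,
`ln Z_s - ln Z_s' = -ln < exp((lambda_s' - lambda_s) ln L) >`, and the
increments telescope from the posterior (lambda = 1) to the prior
(lambda = 0); the final stage's interval reaches 0 exactly, which makes
the telescope complete without sampling the bare prior. The default
ladder steps by 0.01 with 2,000-sweep stages using the last 1,000 -- the
fine spacing is not a luxury: each increment carries a finite-sample
Jensen bias that grows with the spread of `dlambda * lnL`, and the
conjugate-Gaussian oracle test shows a visible upward bias already at
dlambda = 0.05 on a 12-point dataset. Standard errors come from a
bootstrap over walkers within stages. The likelihood entering the ladder
is the fit target itself, including the 4x dephosphorylation weight --
a documented deviation from strict density normalization, constant
across models and therefore harmless to Bayes factors between them.

Model variants tie the KaiA on/off factors across the nucleotide state
(`minus_n`), the phosphoform (`minus_p`), or both (`minus_n_p`, a single
on/off pair: the base `ka`/`kb`). Detailed balance is re-derived per
variant: once a cycle's KaiA factors are tied, its constraint falls on a
KaiA-bound phosphotransfer factor instead, so the variants have 26, 22
and 20 free Delta-k respectively and still balance every cycle exactly.
`kai_variant_project()` produces the matched tied set for a full
parameter set by collapsing each tied group to its geometric mean. Its
`anchor` argument decides what happens to the group absorbed into the
base rates: `"baseline"` (default) leaves it at the bare `ka`/`kb`. For
the ultrasensitivity contrast this is the scientifically meaningful
choice -- the differential affinity *is* the tight ADP-form binding, and
removing the differential removes it. The alternative `"mean"` anchoring
preserves a symmetric ~40 nM U-state trap whose pool-depletion feedback
alone sustains ultrasensitivity, which makes it the wrong control for
that question (both are available; the tests pin both behaviors).

# Stimulus-response analysis

`kai_steady_state_response()` evaluates the phosphorylation reaction at
a fixed long time (24 h, matching the experimental steady-state
determination) across a KaiA grid, with an explicit settledness check
(< 0.1 %/h) rather than a root-finder on the ODE -- the experiments this
mirrors are long fixed-time measurements, and some conditions are only
near steady state. ECx is the stimulus at which the response first
reaches x% of the saturation response above baseline; saturation is the
top-of-grid response guarded by a plateau check (< 1% per decade), the
baseline is the zero-stimulus response (linearly extrapolated when the
grid excludes zero), and crossings are located by monotone Hermite
interpolation plus root refinement. EC10 measures threshold-like
behavior and EC90 - EC10 switch-like behavior; a pure hyperbola
[A]/(K+[A]) has (EC10, EC90 - EC10) = (K/9, 80K/9), so the
switch-to-threshold ratio 80 is the no-ultrasensitivity reference.
`kai_shape_measures()` also fits a matched hyperbolic reference sharing
the curve's own baseline and saturation with only the scale K free; a
free-amplitude fit trades amplitude against scale on switch-like curves
and returns arbitrarily large K, which would make the EC10-versus-K/9
comparison meaningless.

The phenomenological substrate-competition curve
(`kai_competition_curve()`) is the tight-binding-inhibitor scheme: free
kinase from the binding quadratic, then a hyperbola with half-saturation
K1, amplitude Pmax and baseline b. As the inhibitor affinity tightens
(K2 -> 0) it reduces exactly to the right-shifted, thresholded hyperbola
`Pmax ([K]-[I])/(K1+[K]-[I]) H([K]-[I]) + b`; both limits are test
anchors, and convergence at the threshold point itself is O(sqrt(K2)).
EC50 is not a parameter of the scheme and is extracted numerically by
root bracketing on the fitted curve (`kai_fit_competition()`, nonlinear
least squares with multi-start).

# The synthetic-data generator

`kai_generate()` produces datasets with exactly the statistical
structure the likelihood assumes: forward-model trajectories under known
ground-truth parameters plus i.i.d. Gaussian noise with one global
standard deviation (default 2 percentage points, a typical densitometry
repeatability scale), values clipped to [0, 100] after noise (the
likelihood ignores the clipping -- a documented approximation). The
default design mirrors the real fitting campaign: 6 KaiA levels x 3 %ATP
levels x 8 phosphorylation time points (0-24 h including the 12.25 h
near-steady-state time; only that anchor time is documented, the others
are this package's choice), a 21-point dephosphorylation series on
[0, 20] h generated through the two-stage pull-down protocol (3.4 uM
KaiC phosphorylated with 1.3 uM KaiA for 20 h, then all free KaiA and
KaiA-bound states removed), and the hydrolysis bound attached to the
three lowest KaiA levels at 100% ATP. What the generator does *not*
emulate: gel batch effects, per-batch noise scales, densitometry
nonlinearity, or errors in the time axis. Passing recovery tests on
these data therefore demonstrates the estimation machinery, not
robustness to real-data pathologies.

`kai_default_truth()` is built around the substrate-competition
mechanism: KaiA on/off base rates at their measured values, T/S/D
off-factors at the dwell-time prior modes, and the ADP-bound U state
binding KaiA ~3 orders of magnitude tighter than any other state, making
the unphosphorylated pool a stoichiometric KaiA trap. Exchange is slow
on the trapped U pool (the futile exchange-hydrolysis cycle that holds
the trap together requires `kh [U_TP]` to outpace `krDP [KaiA]` below
threshold) and fast on phosphorylated forms, so that once the trap
saturates, free KaiA stabilizes T/S/D efficiently and the response
switches on sharply. Hydrolysis is slower on phosphorylated TP states --
they revert through phosphotransfer of the bound ADP, not through their
own hydrolysis -- which also keeps the 12 h ADP production of the truth
(~27 uM) under the measured bound (~52 uM). The resulting curve is
threshold-hyperbolic with EC10 about 5-6 times the matched-hyperbola
K/9 at every %ATP, the threshold scales inversely with %ATP, and the
nucleotide-tied projection of the same truth collapses to near the
hyperbolic reference -- the package's computational restatement of the
differential-affinity claim.

# The oscillator module

For metabolic-compensation scans the package ships a monomer-cycle
oscillator: the classic measured phosphoform cycle (U -> T -> D -> S ->
U with KaiA-stimulated Michaelis-Menten rates, half-saturation 0.43 uM
active KaiA) extended with explicit KaiB-bound states and two
modifications under study -- a finite KaiA sequestration affinity and an
ultrasensitive phosphorylation threshold. KaiB binds the S phosphoform
(pseudo-first-order in excess KaiB); the bound complex keeps cycling
(BS <-> BD) and releases KaiB on unbinding or on dephosphorylation back
to U. Sequestration is a one-site quasi-equilibrium with dissociation
constant K_D over the sites carried by sequestration-competent
complexes; `K_D = 0` recovers the infinite-affinity `max(0, A - cap)`
rule.

Two reconstruction choices deserve emphasis, because the source
oscillator's own equations are not restated here and the shipped
constants are a declared stand-in. First, sequestration capacity counts
the S-state complex only (2 KaiA monomers per complex by default;
`bd_sequesters` adds the D-state complex). Counting the D-state complex
makes the capacity rise early in the phosphorylation phase, which
flattens its dependence on the late S phosphoform, removes the phase lag
the negative feedback needs, and leaves the model with a globally stable
fixed point everywhere on the scanned parameter grid. Second, the %ATP
signal enters the phosphorylation steps through the exchange efficiency
`pct/(pct + Krel (100 - pct))` with Krel = 0.25 (ATP preferred at the
pocket); a linear `pct/100` scaling suppresses the day phase so strongly
that the unpatched oscillator dies below 60% ATP, contradicting the wide
oscillatory range the modification study starts from.

The threshold patch replaces active KaiA in the phosphorylation rates by
`max(0, A_active - theta)` with
`theta = theta_c * C_U * (theta_a + (100 - pct)/100)`: the threshold
grows with the unphosphorylated pool and as %ATP falls, the direction
the stimulus-response EC50 scaling dictates. The functional form is an
explicit, config-replaceable stand-in. With `theta = 0` the patch is the
identity, bit-for-bit.

Classification follows fixed rules on the total phosphorylation series
(200 h simulated, first 100 h discarded, resampled at 0.1 h): sd < 0.1
uM is a weak oscillation, trough-amplitude sd > 0.001 uM is damped,
fewer than 3 troughs is an abnormally long period; otherwise the period
is the mean trough-to-trough time, with troughs as local minima of
prominence >= 0.01 uM. The trough/period pipeline is validated on
synthetic sinusoids of known period.

# Scale of the shipped checks

The test suite exercises everything at desk scale: ensemble moments on a
2-D Gaussian (64 walkers, a few thousand sweeps), the evidence oracle on
a conjugate 1-D Gaussian with the 0.01 ladder at 150-sweep stages,
parameter recovery on a 2-coordinate reduction of the model (hydrolysis
rate and the U-state off-rate factor; two phosphorylation conditions
plus a short dephosphorylation series at 0.5% noise) over 10 seeds, and
5 x 5 oscillator scans. The recovery runs widen the stretch parameter to
1.4: at a few hundred sweeps the production value alpha = 1.1 cannot
re-inflate a jitter-collapsed ensemble to the posterior scale, and the
resulting intervals would reflect the sampler's transient, not the
posterior. Full-scale constants (224 walkers, 20,000-sweep annealing
stages, 50,000-sweep sampling runs, the 0.01 evidence ladder with
2,000-sweep stages) live unchanged in the `"paper"` profile.

# Known limitations

* The model is a monomer-level description: no hexamer, no CI-domain
  ATPase, no KaiB binding in the 16-state module, no nucleotide
  depletion, and no direct KaiA-nucleotide interaction.
* The likelihood assumes one global Gaussian error for all records and
  ignores the [0, 100] clipping of percentages.
* The evidence estimator inherits the finite-sample bias of free-energy
  perturbation; trust it only with a fine ladder and check the
  stage-wise diagnostics it returns.
* The oscillator module is a phenomenological reconstruction calibrated
  to qualitative properties (oscillation regions, period near 24 h,
  patch containment), not a quantitative refit of any published scan.
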