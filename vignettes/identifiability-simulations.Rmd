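---
title: "Parameter identifiability simulations for evidence-accumulation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter identifiability simulations for evidence-accumulation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Evidence-accumulation models (EAMs) decompose two-alternative forced
choice behaviour — response times (RTs) and accuracy — into latent
components: how fast evidence accrues (rates), how much evidence is
demanded before responding (thresholds), and time spent outside the
decision process (non-decision time). Inferences drawn from the fitted
parameters are only meaningful when the parameters are *identifiable*:
data generated by the model must pin their values down. When almost all
responses are correct, the data constrain the model almost exclusively
through RTs, and parameter pairs whose *ratio* governs the predictions —
threshold and rate — can trade off nearly freely. `eamrec` implements a
complete simulation pipeline for quantifying this failure mode in the two
dominant EAMs, the diffusion decision model (DDM) and the linear
ballistic accumulator (LBA): generate synthetic datasets at controlled
error rates, refit the generating model by Bayesian
differential-evolution MCMC, and measure how well the generating
parameters are recovered and how strongly they trade off in the
posterior.

## Models

**DDM.** A single Wiener process with drift starts at $z$ between
absorbing boundaries $0$ and $a$ and diffusion coefficient $s = 1$ (the
scaling convention). Across trials the drift is $\mathcal N(v, s_v^2)$
and the start point $\mathrm U(z - s_z/2,\, z + s_z/2)$; observed RT is
the absorption time plus non-decision time $t_0$ (non-decision-time
variability is fixed at $s_{t_0} = 0$, since it has no effect on error
rates). The upper boundary is mapped to the correct response. The
first-passage density is computed from the classic small-time and
large-time series representations of the zero-drift density on the unit
scale, with the representation chosen per evaluation from the number of
terms each needs to reach truncation error below `eps` (default
`1e-10` on the unit scale); the drift distribution integrates out
analytically and the start-point range by Gauss–Legendre quadrature
(default order 16, configurable).

**LBA.** Two deterministic linear accumulators race to a threshold
$b = A + B$; each starts at $\mathrm U(0, A)$ and accrues at a rate
drawn per trial from a normal distribution — mean $v_\text{true}$, SD
$s_{v_\text{true}}$ for the accumulator matching the stimulus; mean
$v_\text{false}$, SD $s_{v_\text{false}} = 1$ (the scaling convention)
for the mismatching one. The defective density of accumulator $i$
winning at time $t$ is $f_i(t)\prod_{j \ne i}(1 - F_j(t))$ in closed
form. Trials on which both rates are non-positive would never terminate;
the package renormalizes the defective densities by
$1 - P(\text{both rates} \le 0)$ and has the simulator redraw such
trials, so densities integrate to one and the likelihood is proper. An
unnormalized variant (`convention = "none"`) is retained for
cross-checks. Numerical guards replace the closed forms by their
limiting expressions when $A$ is numerically zero or a rate SD falls
below $10^{-6}$.

## Sampling data-generating parameters

Data-generating parameter vectors are drawn from truncated multivariate
normal distributions whose correlation matrices come from an empirical
calibration: maximum-likelihood DDM and LBA fits to participants from 17
published 2AFC experiments (580 DDM and 765 LBA estimate sets), with
marginals transformed to a normal shape before the correlations were
estimated. Those correlation matrices ship verbatim in
`ddm_calibration_spec()` / `lba_calibration_spec()`.

The calibration's marginal locations, scales and truncation bounds are
package defaults chosen once to reproduce parameter ranges typical of
the empirical DDM/LBA literature (boundary separation mostly 0.6–2.5,
drift rates 0.5–5, non-decision times 0.1–0.8 s, LBA thresholds and
start ranges of order 0.2–2) *and* to make every target error-rate
scenario reachable by rejection at the study's inclusion margins. They
are plain fields of the spec object and fully editable. Transforms are
log for strictly positive parameters, identity for rate means, and logit
for the DDM relative start point. The LBA mismatching rate mean
`v_false` is truncated below at zero: empirical LBA fits give the
mismatching accumulator a non-negative mean rate, and admitting strongly
negative values would let near-zero error rates arise from a
never-finishing error accumulator — a qualitatively different mechanism
from the threshold/rate regime the calibration represents, and one that
suppresses the `B`–`v_true` trade-off under study.

Two conventions deserve note. First, the DDM start point is sampled (and
fitted) on the relative scale $z/a$, with the start-point range sampled
as $s_z/a$; model objects store absolute evidence units, and
`ddm_params_from_draw()` performs the conversion. The calibration
literature reports the relative quantity, and relative sampling keeps
the start-point support inside the boundaries under correlated draws.
Second, the slow-error regime — error RTs slower than correct RTs — is
enforced by ordering constraints on the sampled vectors: $s_v > s_z$
(evaluated on the sampled relative-range scale) for the DDM and
$s_{v_\text{true}} > s_{v_\text{false}} = 1$ for the LBA. Rejection
sampling (batch proposals from the untruncated MVN, acceptance-rate
guard $10^{-4}$ with the binding criterion named on failure) keeps the
sampler exact and simple.

Conditional sampling — needed by the difficulty and speed–accuracy
designs — uses exact Gaussian conditioning on the transformed scale
followed by the same truncation/constraint rejection.

## Generating datasets at target error rates

`study_design()` encodes the three designs: Study 1 (one stimulus
condition; target error rates 0–50%), Study 2 (easy/medium/difficult at
target ∓2.5%), Study 3 (accuracy/speed instructions at target ∓2.5%),
with trials split equally across conditions (defaults 150, 150, 200;
1200 for the large-trial variants). A candidate dataset is accepted when

* its empirical error rate is within 1% of the target (Study 1) or the
  per-condition absolute deviations sum to at most 2% (Studies 2–3;
  boundaries inclusive) — read as the sum of absolute deviations, the
  strictest defensible interpretation;
* its RT distribution satisfies, in seconds:
  $0.4 \le \text{mean} \le 2.5$, $0.4 \le \text{median} \le 2.5$,
  $0.1 \le \text{IQR} \le 2$, $\max \ge 1.5$, $\min \le 0.5$;
* the slow-error ordering held in the generating parameters.

Candidates are regenerated with fresh parameter draws until acceptance,
up to 100,000 replacements (then an error carrying the per-criterion
failure histogram). The RT criteria are evaluated on the pooled dataset
for the multi-condition designs by default (`rt_pooled`), since nothing
forces a per-condition reading; this is configurable.

Special cases follow the study designs: the DDM 50%-error scenario
replaces the empirically calibrated drift with
$|v| \sim \mathrm U(0.005, 0.05)$, because near-chance drifts have
essentially no mass under the calibration; Study 2 draws one drift per
difficulty uniformly between the 25th and 75th quantiles of the matched
Study-1 scenario's generating drifts (linear-interpolation quantiles,
the package-wide rule) and sorts them so easier conditions get higher
drifts; Study 3 draws one drift, samples the remaining parameters
conditional on it, and then draws the speed-condition threshold
conditional on all non-threshold parameters, rejecting until it falls
below the accuracy threshold. Where a single conditioning value is
needed for Study 2's remaining parameters the mean of the three
condition drifts is used — an open design point resolved here and
documented. DDM datasets generated with $a > 3$ or $v > 5$ (strict) are
excluded from analysis as atypical of empirical work;
`apply_exclusion()` partitions rather than silently drops.

The simulators are exact for the LBA (closed-form race) and
discretized for the DDM: Euler–Maruyama with step $10^{-4}$ s and a 30 s
absorption cap, plus a per-step Brownian-bridge absorption test between
consecutive interior positions. The bridge test matters: the bare scheme
underestimates absorption by $O(\sqrt{dt})$ (about 0.005 in absorption
probability at this step), visible against the analytic error rate at
Monte-Carlo sample sizes of $10^4$ and above. With the correction the
simulator agrees with the quadrature error rate and the
numerically integrated RT distribution at the resolution of the test
suite's Kolmogorov–Smirnov checks.

## Estimation

Each dataset is fit by differential-evolution MCMC: $3k$ chains for $k$
free parameters; proposals
$\theta_i + \gamma(\theta_{r_1} - \theta_{r_2}) + \mathrm U(-\epsilon,
\epsilon)$ with distinct $r_1, r_2 \ne i$, $\gamma = 2.38/\sqrt{2k}$ and
jitter $\epsilon = 10^{-3}$, accepted by a Metropolis step on prior
times likelihood ($-\infty$ likelihoods reject, never crash). Chains
start from prior draws redrawn (cap $10^4$) until the posterior density
is finite.

Chains are initialized with 120 retained samples; while the convergence
diagnostics fail, each round adds samples in steps of 40, discarding
the earliest 40 until the R-hat criterion is met (so the retained window
both sheds transients and grows) and growing thereafter until every
parameter's effective sample size reaches 1000. Convergence requires all
per-parameter R-hat values and the multivariate (largest-eigenvalue)
R-hat below 1.1 and ESS of at least 1000 per parameter; the ESS uses the
spectral-density-at-zero (AR-fit) estimator per chain, summed over
chains. A fit that exhausts `max_rounds` is returned flagged
`converged = FALSE`, never silently.

During burn-in only, a migration sweep (cyclic copying of states among a
random chain subset, Metropolis-accepted, probability 0.05 per sweep)
is interleaved with the DE sweeps. Without it, single outlier chains in
the weakly identified low-error regimes decay extremely slowly and the
R-hat criterion becomes unreachable in practical time; migration during
burn-in is standard practice for this sampler family. Setting
`p_migrate = 0` restores the pure DE kernel.

Priors are independent truncated normals, shipped as presets
(`"ddm-tran-widened"`, `"lba-evans-widened"`) centred on values typical
of the empirical literature with variances inflated (default factor 16,
i.e. SDs multiplied by 4, configurable). The default was set by an
a-priori standard: each prior SD should span the empirically plausible
range of its parameter, so that posteriors in the weakly identified
low-error regimes are shaped by the likelihood ridge rather than the
prior. This matters scientifically: with narrower priors the
threshold–rate trade-off that motivates the whole analysis is partly
masked by prior curvature, and the hallmark low-error overestimation of
thresholds and rates disappears — the prior, not the data, is then
doing the estimating. The DDM is fitted on
$(a, v, z/a, s_v, s_z, t_0)$; the LBA on
$(A, B, v_\text{true}, v_\text{false}, s_{v_\text{true}}, t_0)$. The
difficulty design estimates separate rates per condition and the
speed–accuracy design separate thresholds, mirroring the generating
designs.

## Recovery and trade-off statistics

Point estimates are marginal posterior medians pooled over chains.
Across datasets the package reports, per parameter: the Pearson
correlation between generating values and estimates (undefined
correlations — zero variance — are explicit NA sentinels with reasons),
$\mathrm{RMSD} = \sqrt{\tfrac1n \sum (x_\text{true} -
x_\text{est})^2}$, and the 2.5th/97.5th quantiles of the absolute
deviations. Trade-offs are measured per dataset by pairwise Pearson
correlations between the pooled marginal posterior draws and by partial
correlations from the inverse correlation matrix (pseudo-inverse
fallback with a flag when singular). Ratio recovery ($v/a$, LBA
$v_\text{true}/B$) uses the posterior median of the per-draw ratio as
the estimate — the per-draw ratio respects the posterior dependence that
motivates the ratio in the first place — with the ratio-of-medians
variant exposed for comparison; near-zero denominators are excluded with
a count. A post hoc group-difference summary compares differences of
group means of posterior medians with the true mean differences.

All quantiles package-wide use linear interpolation (R type 7).

## What the generator emulates — and what it does not

The synthetic data reproduce the structure of single-subject 2AFC
sessions: stationary parameters within a condition, independent trials,
RT distributions screened to empirically typical ranges, and a
between-subject parameter correlation structure taken from the empirical
calibration. They do not contain contaminant RTs, attention lapses,
sequential dependencies, practice or fatigue drifts, or
condition-specific non-decision time. Passing recovery checks on these
data therefore bounds what can be expected under ideal conditions; they
say nothing about robustness to contamination or model misspecification.

## Problem sizes and numerical choices in the shipped checks

The full factorial study (two models × up to 10 error rates × two trial
counts × 100 datasets, all fit to the default convergence criteria) is a
cluster-scale computation. The shipped test suite and
`scripts/acceptance.R` run the same pipeline at sizes chosen for a
single desktop core: 20 (tests) or 12 (script) datasets per cell,
shortened sampler runs (ESS threshold 100–150, at most 60 add/remove
rounds, start-point quadrature order 8 inside the likelihood), simulator
oracle checks at $3\times10^4$–$10^6$ draws with Kolmogorov–Smirnov
criteria scaled to the draw count, and calibration-sampler checks at
$10^5$ draws. Posterior medians and the qualitative contrasts they feed
are insensitive to the shortened runs; the default settings reproduce
the full convergence protocol.

## Known limitations

* Estimation is single-subject; hierarchical shrinkage is out of scope.
* Non-decision-time variability is fixed at zero throughout.
* Only the correlation structure of the original empirical calibration
  is available; the shipped marginal defaults are documented stand-ins,
  so quantitative recovery values are comparable in kind to published
  identifiability studies, not cell-by-cell.
* The DDM simulator is discretized (see above); its bias after the
  bridge correction is below Monte-Carlo resolution at the sizes used
  here but not exactly zero.
* Accumulator-specific LBA thresholds/start ranges and more than two
  response alternatives are unsupported.
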