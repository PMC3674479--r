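---
title: "Bayesian inference of short-term synaptic plasticity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian inference of short-term synaptic plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stpbayes)
```

## The model

Short-term plasticity (STP) is the transient change in synaptic efficacy —
depression or facilitation over tens of milliseconds to seconds — produced
by recent presynaptic activity. `stpbayes` implements the Tsodyks–Markram
phenomenological model family. Two state variables evolve between and
across presynaptic spikes: the available resource fraction $R(t)$ (vesicle
pool), which is depleted by release and recovers towards 1 with the
depression time constant $D$, and the release probability $u(t)$, which
jumps by $f\,[1 - u]$ at every spike and decays back to its baseline $U$
with the facilitation time constant $F$.

Rather than integrating the differential equations numerically, the
package uses the exact between-spike recursion: with inter-spike interval
$\Delta t_n$,

$$R_{n+1} = 1 - [1 - R_n(1 - u_n)]\,e^{-\Delta t_n / D}, \qquad
  u_{n+1} = U + [u_n + f(1 - u_n) - U]\,e^{-\Delta t_n / F},$$

with $(R_1, u_1) = (1, U)$ and the postsynaptic potential amplitude
$\mathrm{PSP}_n = A\,R_n\,u_n$, where $A$ (mV) absorbs the number of
release sites, receptor properties and dendritic filtering. Release and
depletion at spike $n$ use the *pre-jump* $u_n$ — the facilitation
increment only influences later spikes, so $\mathrm{PSP}_1 = A\,U$ always.
We verified this indexing convention two ways: the recursion agrees with
dense forward-Euler integration of the continuous-time equations (the test
suite checks relative agreement better than $10^{-3}$ at
$dt = 10^{-5}$ s on all five canonical regimes), and it reproduces the
reference Every Pulse Ratios of the five regimes (see below); all
alternative jump orderings we tried (post-jump depletion, jump before
release, decay-then-jump) break at least two regimes.

Three variants of the model are exposed:

* `"etm"` — the extended model with all four free parameters
  $\{D, F, U, f\}$;
* `"tm_fac"` — facilitation tied, $f = U$ (three parameters);
* `"tm"` — depression only, $u(t) \equiv U$ (two parameters).

Degenerate time constants below $10^{-9}$ s are rejected outright rather
than approximated, to avoid overflow in $e^{-\Delta t/\tau}$.

Summary statistics: the paired-pulse ratio
$\mathrm{PPR} = \mathrm{PSP}_2/\mathrm{PSP}_1$ and the Every Pulse Ratio
(EPR), the mean of successive amplitude ratios over the whole train.
EPR < 1 indicates net depression, EPR > 1 net facilitation. The five
presets in `regime_presets()` span strong depression
(EPR $\approx 0.45$) to strong facilitation (EPR $\approx 1.43$) for five
pulses at 30 Hz; four of the five reference EPRs match the recursion to
two decimals exactly, the facilitation–depression regime computes to
0.9460 against a reference of 0.94 (agreement at the printed precision;
we attribute the residual 0.006 to rounding in the reference table, as no
defensible integration convention reproduces it exactly while preserving
the other four).

## Stimulation protocols

`periodic_train()`, `recovery_train()` and `poisson_train()` generate the
protocols compared in the protocol-evaluation module. The recovery train
appends pulses whose delays after the periodic segment are geometrically
spaced from one inter-spike interval up to the recovery span. "Spaced
exponentially" is under-specified in the source material; we chose a
log-uniform (geometric) progression because it probes recovery at
multiple timescales and reproduces the documented total duration of
$7/30 + 4 \approx 4.23$ s for 8 pulses at 30 Hz with 9 recovery pulses
over 4 s. Poisson trains are defined by event *count*, not duration, so
that protocols are compared at matched numbers of spikes; an optional
absolute refractory period (default 0) is available since the source
protocol does not state one.

## Noise model and the synthetic-data generator

The observation model is Gaussian and independent across pulses: the
per-pulse mean amplitude $d_i$ is normal around the model prediction with
standard deviation $\sigma_i$. Apparently negative amplitudes are valid
data under this model and need no special treatment.

`make_noisy_train()` emulates a standard acquisition: `n_sweeps` sweeps
per pulse with sweep-to-sweep coefficient of variation `cv`, averaged to
per-pulse means. Defaults are `n_sweeps = 30` (experimental recordings of
this kind average 20–40 sweeps) and `cv = 0.5` (typical for these
synapses). Two noise-scale conventions are provided because the
literature is ambiguous: `sigma = "se"` (default) stores the standard
error of the across-sweep mean, $cv \cdot a_i / \sqrt{n}$, which is the
statistically coherent uncertainty for a mean; `sigma = "sd"` stores the
raw sweep-level standard deviation, matching a literal reading of the
likelihood with per-sweep CVs. Both use the known generative noise level,
as an experimenter would estimate it from the sweep histogram.

The generator also has an `data = "expected"` mode that returns the
noiseless model amplitudes with the assumed noise level attached. This is
the design-stage idealization used for protocol scoring (below). What
the sampled generator does **not** emulate: stochastic vesicle release
correlations (a separate binomial-depletion generator,
`make_stochastic_release_train()`, exists for that), amplitude-dependent
CV trends, recording drift, and miniature events. Passing tests on this
generator therefore demonstrate correctness of the inference machinery
under the stated noise model, not robustness to every artifact of real
recordings.

`make_cohort()` draws class-conditional parameters from truncated
Gaussians inside the prior box. The default specs emulate three
neocortical excitatory connection classes: depressing pyramidal-to-
pyramidal (PC–PC, $U \approx 0.53$) and pyramidal-to-basket
(PC–BC, $U \approx 0.72$) connections and facilitating
pyramidal-to-Martinotti (PC–MC) connections with small $U$, $D$ and $f$.
The class means for $U$ follow reported experimental estimates; the
remaining means follow the matching simulated regimes, and the spreads
are our choice (documented in `default_class_specs()`). The true
experimental parameter distributions are unknowable from published
summaries; this cohort is explicitly a synthetic stand-in.

## Posterior inference

Priors are independent and flat: $D, F \sim U[0, 2]$ s,
$U, f \sim U[0, 1]$. The amplitude $A$ is *profiled out analytically* by
default: at every likelihood evaluation $A$ is set to its closed-form
weighted-least-squares optimum
$\hat A = \sum_i d_i m_i/\sigma_i^2 \,/\, \sum_i m_i^2/\sigma_i^2$ for
the candidate dynamics parameters ($m_i$ the normalized model values).
$A$ carries no information about the dynamics, and profiling avoids a
fifth sampling dimension; `amplitude = "sample"` instead samples $A$
explicitly with a flat prior up to ten times the largest absolute data
amplitude.

Sampling is coordinate-wise slice sampling — stepping-out then shrinkage,
in the fixed order $D, F, U, f$, one sweep per iteration — with initial
slice widths equal to the prior widths $\{2, 2, 1, 1\}$. The stepping-out
interval is clipped to the prior box, so the sampler is rejection-free.
Defaults: 3 chains of 10,000 iterations, the first 2,500 discarded as
burn-in, retaining 22,500 samples. Chains start from independent uniform
draws in the box (re-drawn if the target is $-\infty$ there). A target
evaluating to `NaN` is a hard error. Convergence is summarized by the
Gelman–Rubin potential scale reduction factor, treated as a warning
diagnostic (values well above ~1.1 indicate trouble; small values cannot
prove convergence).

The MAP estimate is the best retained sample across chains; an optional
bounded local refinement (`refine = TRUE`, off by default) may only
improve the log-posterior. Posterior marginals use a Gaussian kernel
density estimate with Scott's bandwidth on a uniform grid over the prior
support, truncated at the bounds and renormalized to integrate to one by
the trapezoid rule. Because the four-dimensional posterior has parameter
dependencies, the MAP can sit away from the marginal peaks; the test
suite checks that the joint MAP is never worse than the vector of
per-marginal argmaxes.

## The traditional baseline

`sa_fit()` is the least-squares baseline: best-of-`n_restarts`
(default 200) simulated annealing of the non-variance-scaled RMSE,
constrained to the prior box, with $A$ profiled by ordinary least squares
(a variance-scaled objective is available by flag). The annealing
schedule is not specified in the source; ours is geometric cooling
($T_k = T_0\, 0.95^k$), Gaussian proposals of scale $0.1 \times$ the
prior width, 500 steps per restart, followed by a Nelder–Mead polish of
each restart's best point — the polish makes every restart converge to a
local optimum, which is what exposes the characteristic degeneracy: on a
five-pulse depressing train every restart reaches an excellent fit
($R^2 > 0.99$ on data the model can represent) while the fitted $F$
scatters across most of its prior range. All schedule constants are
arguments.

## Protocol evaluation and model selection

The sample estimation error of a posterior against known parameters is
$E = \langle \sum_{i} [(\theta_i - \theta^*_i)/\theta^*_i]^2 \rangle$,
averaged over all retained samples; it penalizes both bias and posterior
spread. Prior-width normalization is available for zero-valued true
parameters. `compare_protocols()` averages $E$ over the five canonical
regimes and over seed replicates (default 3).

Protocol scoring defaults to the *expected-data* mode: the inference runs
on the model's noiseless amplitudes with the assumed noise level, so $E$
measures exactly the posterior spread a protocol permits — this is the
design-stage question ("which stimulus constrains the parameters?"), and
it is why the error approaches zero for a long Poisson train while a
1000-pulse *periodic* train plateaus: the periodic response reaches
steady state after a few pulses and additional pulses add no new
information, whereas Poisson intervals probe recovery across timescales.
A sampled-noise mode is available to include estimator scatter.

Model selection ranks the three variants by
$\mathrm{AIC} = 2k - \log P(\theta_{\mathrm{MAP}} \mid d)$ with the MAP
log-posterior evaluated on amplitude-normalized data ($d_i / \hat A$).
This is deliberately the as-published definition rather than the
conventional $2k - 2\log L$; with flat priors and fixed data the two
differ in ways that do not change within-dataset rankings, and a
`conventional = TRUE` switch is provided. Akaike weights
$w_m \propto e^{-\Delta_m/2}$ and pairwise evidence ratios $w_a/w_b$
summarize the ranking.

## Clustering and classification

Each connection is represented by its four discretized marginal
posteriors on a shared binning: 100 uniform bins per parameter over the
prior support (shared binning is required for comparability), with an
$\epsilon$-floor of $10^{-12}$ before normalization so that divergences
stay finite. Distances between connections are the *sum* over the four
marginals of either the symmetrized Kullback–Leibler divergence or the
Hellinger distance (the mean would only rescale all distances).
Clustering is average-linkage (UPGMA) agglomeration; the number of
clusters is chosen by maximizing the Calinski–Harabasz pseudo-F. For
pseudo-F we use the concatenated discretized marginal vectors as the
feature embedding (the published notation is ambiguous on this point; any
fixed embedding consistent across cuts yields a comparable criterion).
The baseline route clusters z-scored SA point estimates with Euclidean
distance and the same linkage. Clustering quality against known classes
is the dendrogram purity: the expected class-fraction of the
least-common-ancestor subtree over all same-class leaf pairs.

Classification is Naive Bayes with a uniform class prior: the
class-conditional likelihood is the product over parameters of truncated
Gaussian-kernel KDEs (Scott bandwidth, renormalized kernel mass inside
the box, densities floored at $10^{-300}$ before logs) built from the
pooled posterior samples of the class's training connections, evaluated
at the test connection's MAP. Cross-validation follows the
train-on-$K$-per-class scheme: $K$ connections per class (default 7)
build the likelihoods and the held-out remainder is classified; because
enumerating all partitions is combinatorial, we replicate over random
splits (`n_reps`). A per-class $K$-fold mode is provided as the
alternative reading of the published procedure.

## Numerical choices and problem sizes

* Natural logarithms throughout the likelihood machinery.
* Slice-sampler shrinkage aborts (keeping the current point) if an
  interval collapses below $10^{-14}$, a pure floating-point guard.
* The package's own test suite runs the full 3 × 10,000-iteration
  schedule for the headline parameter-recovery check (1000-pulse Poisson
  train) and scaled-down schedules (2,000 iterations, 2 chains) for the
  protocol-ranking and cohort-clustering checks; the synthetic cohorts
  there use 8 connections per class. These sizes were chosen as the
  smallest that exercise the full pipeline meaningfully.

## Known limitations

* The Gaussian noise model ignores release-count correlations between
  successive pulses; the stochastic-release generator exists precisely to
  probe that mismatch (posteriors remain centered but widen somewhat).
* Flat priors bounded at $D, F \le 2$ s truncate genuinely slower
  kinetics; the bounds are arguments where that matters.
* The facilitation time constant $F$ is structurally poorly identified by
  short periodic trains — that is a property of the experiment, not the
  sampler, and is the package's central argument for Poisson or
  recovery-augmented protocols.
* Hierarchical pooling across connections and informative priors are out
  of scope.
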