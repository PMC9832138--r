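---
title: "Decision circuits with choice-selective inhibition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision circuits with choice-selective inhibition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inhibmotifs)
```

# The scientific problem

In two-alternative perceptual decisions, two pools of excitatory cortical
neurons integrate competing streams of evidence; the pool that wins expresses
the choice as a persistently elevated firing rate. Classical attractor models
treat inhibition as a global, unselective pool. Experimental recordings,
however, show inhibitory interneurons that are as choice-selective as
excitatory neurons. `inhibmotifs` implements a family of models in which the
*specificity* of each connection class between choice-selective populations is
a parameter, so that the functional consequences of selective inhibition —
competition, stabilisation, speed-accuracy trade-offs, working memory — can be
studied systematically.

Connection specificity is parameterised per directed class
(excitatory-to-excitatory EE, excitatory-to-inhibitory EI,
inhibitory-to-excitatory IE, and inhibitory-to-inhibitory II in the
four-variable model) by a normalised difference
$$\gamma = \frac{w^+ - w^-}{w^+ + w^-},$$
where $w^+$ and $w^-$ are the mean weights between populations of the same and
of opposite choice preference. The mapping from $\gamma$ to weights
(`specificity_to_weights()`) conserves the total input to every population, so
changing a motif never changes the overall drive. Positive $\gamma_{IE}$
defines an *ipsispecific* motif (inhibition returns to the population that
drove it: a stabilising feedback loop), negative $\gamma_{IE}$ a
*contraspecific* motif (inhibition targets the rival population: lateral
competition), and $\gamma_{IE} = 0$ a nonspecific motif.

# The two-variable model

The slow degrees of freedom are the NMDA gating variables $S_1, S_2$ of the
two selective excitatory populations:
$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_{\mathrm{NMDA}}} +
  (1 - S_i)\,\gamma_k\,\Phi(x_i), \qquad
  \Phi(x) = \frac{a x - b}{1 - e^{-d(a x - b)}},$$
with $\tau_{\mathrm{NMDA}} = 0.1$ s, kinetic factor $\gamma_k = 0.641$, and
gain $(a, b, d) = (270\,\mathrm{nC}^{-1}, 108\,\mathrm{Hz}, 0.154\,\mathrm{s})$.
The input current to population $i$ is
$$x_i = \alpha_1 S_i + \alpha_2 S_j + I_0 + I_{\mathrm{stim},i} + I_{\eta,i}.$$

All other populations (nonselective excitatory, three inhibitory pools) are
linearised away into the effective couplings. `derive_couplings()` assembles
them from the circuit constants: $\alpha_1$ collects the direct self-coupling
$f N_E w^+_{EE} J_{\mathrm{NMDA,eff,E}}$ and the three disynaptic loops
through the same-preference, opposite-preference and nonselective inhibitory
pools (each a product of an E-to-I leg, the linearised inhibitory gain
$c_I / (\kappa\, g_{I2})$ and an I-to-E GABA leg, entering with a negative
sign); $\alpha_2$ collects the same four paths from the rival population; and
$I_0$ collects the nonselective-excitatory drive, external AMPA input, and the
baseline inhibitory rate fed back through GABA synapses. The stimulus raises
the external input rate by $\mu = 40$ Hz split by the signed coherence $c$
(percent): $I_{\mathrm{stim},i} = J_{\mathrm{AMPA,ext}}\,\mu\,(1 \mp c/100)$
while on, so positive coherence favours population 2.

With the defaults ($\gamma_{EE} = 0.32$, $\gamma_{EI} = 0.25$,
$\gamma_{IE} = 0$, $\nu_{0,I} = 11.5$ Hz, $f = 0.15$), the couplings come out
as $\alpha_1 = 0.262$ nA, $\alpha_2 = -0.052$ nA, $I_0 = 0.324$ nA, and the
phase planes carry the eight fixed points that define a decision-competent
circuit: unstimulated, a symmetric low-rate attractor, two working-memory
attractors and two saddles; stimulated at $c = 0$, two choice attractors
separated by one symmetric saddle.

```{r census}
p <- circuit_params()
find_fixed_points(p)
```

## Calibration of the effective couplings

Two effective conductances are calibration constants of this package rather
than literal physiological values, because the tabulated circuit constants
are not mutually consistent with the reduction scalings
($\lambda_1 = 1.6719$, $\lambda_2 = 1.8844$, $\lambda_I = 0.9229$): taken
verbatim they produce couplings an order of magnitude too strong and no
decision structure at the reference circuit. Two independent anchor equations
(requiring $\alpha_1$ and $\alpha_2$ at the reference circuit to equal the
canonical two-variable reduction values that the $\lambda$ scalings
presuppose, roughly $0.261$ and $-0.050$ nA) pin the inhibitory loop gain to
within 1% of each other, which fixes `g_E_rec_GABA_loop` (effective loop
coupling $J = 0.478$ nA). The background leg must carry its own constant,
`g_E_rec_GABA_bg` ($J = 0.217$ nA), chosen once so that the background current
$I_0(\nu_{0,I})$ places the eight-fixed-point window at the centre of the
stated operating range of the inhibitory baseline: $I_0(11.5) = 0.324$ nA,
the middle of the window $[0.321, 0.327]$ measured with the final couplings.
This makes the slow saddle time constant U-shaped in $\nu_{0,I}$ with its
minimum near $12.9$ Hz, so the low- (11.5 Hz) and high- (14 Hz) inhibition
baselines sit on opposite branches. Both constants are ordinary entries of
`circuit_params()` and can be overridden.

## Noise and reported rates

Noise enters as an AMPA-filtered Gaussian current per population,
discretised as
$$I_\eta(t + \Delta t) = I_\eta(t)\Big(1 - \tfrac{\Delta t}{\tau_A}\Big) +
  \sqrt{\Delta t}\,\frac{\sigma}{\sqrt{\tau_A}}\,\mathcal{N}(0, 1),$$
with $\sigma = 0.02$ nA and $\tau_A = 2$ ms. At the default step
$\Delta t = \tau_A$ the two readings of $\sigma$ (white-noise amplitude versus
stationary standard deviation) coincide: the discretised process is white with
stationary s.d. $0.02$ nA. Both conventions remain available through
`noise_convention` for other step sizes, with the closed-form stationary s.d.
exposed by `noise_stationary_sd()` as the oracle used in the tests.

Because the discretised noise current is white, the instantaneous
transfer-function output flickers by several Hz from step to step. The
*reported* population rates are therefore the read-out of the slow NMDA state
(the transfer function applied to the state-driven input current, noise
excluded); the noise current still drives the dynamics and is recorded in its
own trajectory columns. Evaluating the behavioural criteria on the raw
flickering rates would invalidate nearly all trials of *any* circuit through
spurious pre-stimulus excursions, destroying the motif-specific structure of
trial failure that the model is built to expose; with the state read-out,
premature separation occurs exactly when the pre-stimulus dynamics are
genuinely unstable (strongly contraspecific motifs), and completion,
psychometric and chronometric curves take their expected shapes.

## Behavioural evaluation

A trial is *valid* when (i) the absolute rate difference stays below 5 Hz at
every pre-stimulus step and (ii) it reaches the 15 Hz decision threshold at
some step of the stimulus window or at the first post-offset point (the
stricter conjunctive reading is available via `rule = "and"`). The choice is
the population leading at the first qualifying crossing; decision time is that
crossing minus stimulus onset, at one-step (2 ms) resolution. Invalid trials
keep their failure reason and are never assigned a choice. Accuracy and
chronometric summaries use valid trials only; the completion fraction counts
valid trials out of all presented. The default schedule is 0.5 s pre-stimulus,
1 s stimulus, 1 s delay; trials start at $S_1 = S_2 = 0.1$ (inside the
low-state basin) with zero noise current — all configurable.

Perturbation experiments shift $\nu_{0,I}$ by up to $\pm 0.5$ Hz during the
stimulus window only. By default all levels reuse the same random streams
(common random numbers), which makes the deltas paired differences with very
small Monte-Carlo error; because a small background shift almost never flips
the choice on a paired trial, accuracy deltas under common random numbers are
exactly zero, so `crn = FALSE` provides independent streams when accuracy
effects are of interest. Random streams are drawn per condition batch (one
derived seed per coherence level), so common random numbers hold whenever the
per-condition trial counts match.

## What the two-regime analysis does and does not reproduce

The saddle time constant $\tau_{\mathrm{slow}}$ (inverse of the positive
Jacobian eigenvalue) behaves as expected throughout: it rises strictly with
$\gamma_{EI}\gamma_{IE}$ until the stimulated saddle becomes an attractor,
rank-correlates with decision time across inhibitory motifs, and is U-shaped
along $\nu_{0,I}$ with the two baselines on opposite branches. The behavioural
consequences of baseline perturbations, however, only partially follow
$\tau_{\mathrm{slow}}$ in this calibration: the completion fraction reverses
sign between the baselines (up at 11.5 Hz, down at 14 Hz when inhibition is
enhanced), and at the high baseline all three effects (slower decisions, fewer
completions, higher accuracy) appear; but mean decision time and accuracy are
monotone in the inhibitory baseline everywhere we probed (noise s.d.
0.002-0.02 nA, every placement of the fixed-point window), because the
perturbation enters the reduced dynamics only through the background current,
along which the slow passage near the lower saddle-node and the overall rate
level dominate threshold crossing. The corresponding acceptance expectations
at the low baseline are left failing rather than weakened; the completion
reversal and the high-baseline triple are asserted and hold.

# The four-variable model

`fourvar_params()` adds explicit GABA gating variables for the two selective
inhibitory populations, enabling inhibitory-inhibitory specificity
$\gamma_{II}$:
$$\frac{dS_i}{dt} = -\frac{S_i}{\tau_{\mathrm{NMDA}}} + (1 - S_i)\gamma_k
\Phi_E(x_i) \;(i = 1, 2), \qquad
\frac{dS_i}{dt} = -\frac{S_i}{\tau_{\mathrm{GABA}}} + \Phi_I(x_i)\;(i = 3, 4),$$
with population-specific gains and a 4x4 coupling matrix built from the same
specificity-to-weight mapping (`fourvar_adjacency()`). The synaptic constants
and background currents are fixed model data (`J_NMDA,E` = 0.4235 nA,
`J_NMDA,I` = 0.5743, `J_GABA,E` = -0.4699, `J_GABA,I` = -0.6421,
`I_0,E` = 0.7707, `I_0,I` = 1.0267); the upstream calibration that produced
them is not re-run here. On the noiseless reference trial at stimulus strength
0.05 — interpreted as coherence 0.05% with the standard 40 Hz stimulus; the
direct-current reading can be emulated by overriding `J_AMPA_ext` — the
excitatory rate traces of the four- and two-variable models agree within 3 Hz
(the package's regression bound; the measured maximum difference is about
2.4 Hz). Simulations start the inhibitory gating on its fast steady-state
manifold (`fourvar_settle_inhibition()`); starting it elsewhere only injects
an artificial millisecond transient. Noise (s.d. 0.2 nA) enters the inputs of
all four populations. The four-dimensional fixed-point search uses the same
damped-Newton multistart machinery with an analytic Jacobian, with the
classification applied to the excitatory projection. Strongly negative
$\gamma_{II}$ (hyper-competitive inhibition) removes the low-activation
attractor, while moderate $\gamma_{II}$ of either sign leaves the
decision structure intact.

# Fixed points, stability and bifurcations

`find_fixed_points()` runs a damped Newton iteration with the closed-form
Jacobian from a multistart grid (21x21 over the unit square plus nine
canonical seeds), deduplicates roots within $10^{-4}$ and verifies
$\max |dS/dt| \le 10^{-6}$ at every accepted root. A per-start
Levenberg-Marquardt solver (`method = "lm"`, via \pkg{minpack.lm}) is kept as
an independent cross-check — the tests assert both solvers find identical
root sets — while the vectorised Newton path is the default because
specificity-space scans classify thousands of circuits. Stability comes from
the eigenvalues of the analytic Jacobian; a saddle's `tau_slow` is the inverse
of its positive eigenvalue. Labeling uses a 0.1 Hz rate-symmetry tolerance
(far below the 15 Hz decision threshold) and a 15 Hz ceiling for the low-state
attractor; ambiguous labelings (e.g. two symmetric attractors) are flagged
indeterminate rather than resolved silently. `bifurcation_sweep()` links
fixed points across parameter values by nearest-neighbour continuation and
localises signature changes by bisection to a $10^{-4}$ bracket; the sweep
"stimulus strength" convention is the coherence of the standard 40 Hz
stimulus, so `stim = 0` means stimulus on at zero coherence.

# The excitatory-inhibitory recurrent network

`rnn_params()` configures the discrete-time Dale-constrained rate network
(100 excitatory, 25 inhibitory units; 60-step trials; 21-step stimulus with
per-trial onset drawn uniformly while keeping at least 10 pre- and
post-stimulus steps). Inputs follow leaky filtering with rate
$\alpha_{in} = 0.2$; recurrent units leak with $\alpha_r = 0.2$; rates are
slope-scaled rectifications; only excitatory units receive inputs and drive
the two outputs. Recurrent noise is scaled by $\sqrt{2\alpha_r}\,\sigma_{0,r}$
and input noise by $\sqrt{2/\alpha_{in}}\,\sigma_{0,in}$ — the two
scalings are asymmetric by design and implemented as given. Initial weights are
Gamma-distributed (shape 0.0375, scale 0.5; inhibitory-source matrices scaled
by $\theta = N_E s_E / N_I s_I$), input/output weights normalised to unit
sums. Training minimises a masked mean squared output error (stimulus steps of
non-catch trials are excluded from the error so the network must hold its
decision after offset) plus L2 activation and L1 weight penalties, by
backpropagation through time with hand-derived gradients (verified against
finite differences in the tests), adaptive-moment updates at learning rate
0.01 with global gradient-norm clipping at 1, and after every step a
projection to nonnegative weights and zero self-connections. Half of each
200-trial epoch are catch trials; difficulty is sampled from the +-2..20
levels (continuous-uniform sampling is available via `difficulty_sampling`).
Validation after every epoch uses 100 trials spanning coherences -20..20 in
steps of 2, the 0.25 output-difference decision threshold, the 75%/50%
pre/post-stimulus validity rules, and the performance definition that excludes
the ambiguous zero-coherence level (the all-trials variant can be obtained by
rescaling); training stops at 85%.

Choice selectivity is measured per unit as the ROC area for decoding the
network's choice from the unit's activity at the step following stimulus
offset, over the valid trials of a fresh 200-trial evaluation batch, with a
150-permutation two-sided significance test at the 2.5% tails; the index is
$|AUC - 0.5|$. The AUC is computed by the exact rank formula and cross-checked
against trapezoidal ROC integration in the tests. Connection specificity per
class is the same normalised difference $\gamma$ applied to mean weights
between significantly selective units, matching presynaptic to postsynaptic
preference and excluding self-connections.

## Reproducibility and emergent connectivity

All randomness derives from one master seed through a counter scheme
(`derive_seed()`), so training runs are exactly reproducible. Networks trained
with this implementation reach the 85% criterion in roughly 70-190 epochs
(14k-38k trials) and consistently develop a *contraspecific* output motif:
$\hat\gamma_{IE} \approx -0.4$ to $-0.5$ with $\hat\gamma_{EE} \approx
0.4$-$0.7$ across seeds. The inhibitory units are more choice-selective than
the excitatory ones (by index and by fraction significant), and across
networks $\hat\gamma_{EE}$ correlates positively with
$\hat\gamma_{EI}\hat\gamma_{IE}$ — the same complementarity the mean-field
analysis predicts — but the ensemble sits at the contraspecific end of that
line rather than centring on a nonspecific output motif. We probed and
rejected two levers (continuous difficulty sampling; training 2.5x longer to a
stricter criterion): the basin is robust under this implementation. Emergent
connectivity in these networks is known to be highly sensitive to training
hyperparameters that are rarely fully specified (difficulty distribution,
onset margins, optimizer internals); results about the *sign balance* of the
output motif should be read with that caveat.

# Synthetic data and what passing tests show

All inputs are generated programmatically: stochastic trials from the
mean-field generators, task batches from `make_batch()`, and ground-truth
fixtures from `make_fixture()` (step-profile trajectories with prescribed
crossing times, planted block weight matrices with exact specificities,
two-group activities with closed-form ROC areas). The generators emulate the
study conditions — stationary Gaussian input noise, fixed trial epochs, a
stationary task — and none of the nonstationarities of real recordings
(adaptation, slow drifts, correlated noise across populations, measurement
noise). Passing tests therefore certify the implementation of the models and
analyses, not the behaviour of biological circuits.

# Problem sizes used by the standard checks

The bundled checks run at desk scale, chosen to exercise every pipeline at
meaningful statistical resolution: fixed-point censuses on 21x21 multistarts;
a 15x9x17 specificity scan; behavioural sessions of 100-500 trials per
condition; perturbation contrasts at n = 500 per coherence and level; three
trained networks for the replication statistics. The full-scale replication
(many tens of networks) is supported by the same functions with larger
`n_networks`.

# Known limitations

* The two calibrated background/loop conductances make the reference circuit
  and operating range exact by construction; absolute positions of scan
  boundaries inherit that calibration.
* Along the inhibitory-baseline axis, decision time and accuracy do not
  reverse between the two regimes in this calibration (completion does); see
  the two-regime section.
* The trained networks' output-motif sign balance differs from nonspecific;
  see the reproducibility section.
* Decision times are resolved at one integration step; no sub-step
  interpolation is attempted.
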