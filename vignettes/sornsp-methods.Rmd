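---
title: "Self-organizing recurrent spiking networks with structural plasticity: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organizing recurrent spiking networks with structural plasticity: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sornsp)
```

## The model

`sornsp` simulates a discrete-time recurrent network of binary threshold
neurons whose connectivity and weights are shaped jointly by four
plasticity mechanisms, and evaluates it on periodic sequence-learning
benchmarks.

The network has three populations: $N^E$ excitatory and
$N^I = 0.2\,N^E$ inhibitory neurons form the recurrent layer, and one
output neuron per task symbol forms the readout layer. A neuron fires
($s = 1$) when its summed input reaches its threshold:
$s_i(t+1) = \Theta(\psi_i(t) - \theta_i)$ with $\Theta(0) = 1$. Four
weight matrices connect the populations: sparse plastic $W^{EE}$ with a
binary mask $c_{ij}$ (no self-connections), dense fixed $W^{EI}$ and
$W^{IE}$, and dense plastic readout $W^{OE}$. There are no
inhibitory-to-inhibitory connections. All weights are drawn uniformly
from $[0,1]$ at initialization and every afferent row is normalized to
sum to one.

Each input symbol drives a fixed, disjoint subset of excitatory neurons
with unit amplitude; all other neurons receive no external input. With
thresholds initialized in $(0, 0.5]$, a unit drive guarantees that a
symbol's subset can fire, which makes the input subsets reliable anchors
of the recurrent dynamics. The subset size defaults to 5% of the
excitatory population (at least 10 neurons): the subsets are what entrain
the recurrent orbit to the task period, and a fixed absolute size would
make the entrainment weaker — and period locking less reliable — as the
network grows.

### One step of the dynamics

All populations update synchronously from pre-step values:

1. inhibitory response: $s^{in}(t+1) = \Theta(W^{IE} s^e(t) - \theta^{in})$;
2. excitatory update:
   $s^e(t+1) = \Theta(W^{EE} s^e(t) - W^{EI} s^{in}(t+1) + u(t) - \theta^e)$;
3. output potentials: $\psi^o = W^{OE} s^e(t) - \theta^o$; the read-out
   symbol is the argmax of $\psi^o$ (ties resolve to the lowest index).

The inhibitory term in step 2 deserves comment, because it is a genuine
design choice. If the excitatory update instead uses the *previous*
inhibitory state $s^{in}(t)$ (computed from $s^e(t-1)$), inhibition lags
excitation by one full step and the excitatory population enters a
boom-bust limit cycle: activity within one task period swings between
saturation and complete silence, and at the silent phase steps the state
carries no information for the readout. We observed exactly this failure
mode, with per-step active counts like 9/35/107/44/0/1 repeating
periodically on the counting task. Computing the inhibitory response from
the same $s^e(t)$ that supplies the recurrent drive ("fast feedforward
inhibition", step 1 before step 2) balances each update internally and
yields stable, informative states. Both readings are consistent with the
model's discrete-time formulation; the package implements the stable one.

### Reward-modulated STDP with eligibility traces

Plastic weights change only when the reward deviates from its running
baseline:
$$W(t+1) = W(t) + \eta\, M\, e, \qquad M = R - b,$$
where $e$ is a per-synapse eligibility trace updated by one forward-Euler
step per tick,
$$e_{ij} \leftarrow e_{ij}\left(1 - \tfrac{1}{\tau_e}\right)
  + s_i(t)\,s_j(t-1) - f\, s_i(t-1)\,s_j(t),$$
with $i$ post- and $j$ pre-synaptic, $f = 1$ for $W^{EE}$ and $f = 0.01$
for $W^{OE}$. Weights are floored at zero and the afferent rows of the
plastic matrices are renormalized to sum to one after every update
(synaptic normalization). The baseline $b$ is an exponential moving
average of the reward, $b \leftarrow (1-\alpha) b + \alpha R$ with
$\alpha = 0.05$ by default; an EMA needs $O(1)$ state and leaves the
neuromodulation factor smooth.

**Trace length.** The default is $\tau_e = 2$ steps. Because a reward
arrives *every* step in these tasks, the trace must stay short relative
to the task period: with a long trace (say $\tau_e = 15$ against a period
of 6) the coincidence stored at a rewarded step is still present — merely
decayed — at the following unrewarded steps, and the negative
neuromodulation there cancels almost exactly the potentiation it just
received. In long control runs with $\tau_e = 15$ the readout weights
reach a fixed point at the trivial always-predict-the-majority solution
and stay there for millions of steps. Long traces are the right tool for
*delayed* rewards; for dense per-step rewards the trace only needs to
bridge the one-step gap between a coincidence and its reward.

**Output credit assignment.** The output layer competes winner-take-all:
the neuron with the largest potential spikes and emits its symbol, and it
is this one-hot activity that enters the eligibility trace and the output
intrinsic plasticity. This gives the three-factor rule per-neuron credit —
on a wrong step exactly the wrongly-winning row is depressed, and on a
correct step exactly the winning row is potentiated. If instead all
outputs whose potential crosses threshold are treated as active in the
trace, a near-miss (right winner, spurious runner-up spike) depresses the
correct output's just-formed coincidences as well; empirically the
readout then oscillates indefinitely between solving and unsolving the
hard transition instead of settling. `step_output()` still exposes the
thresholded binary output states and the raw potentials.

Prediction reward: the read-out emitted at step $t$ (computed from the
state that saw the input at $t-1$) is compared with the symbol presented
at step $t$; $R = 1$ if they match, else 0 (default) or $-1$. The $-1$
scheme learns easy tasks faster but its strong negative neuromodulation
keeps reshaping the recurrent weights on hard tasks, preventing the
reservoir orbit from ever stabilizing; the 0 scheme scales the error
signal with the recent success rate and is the robust default.

The recurrent and readout learning rates are exposed separately
($\eta$, $\eta_{oe}$; both default 0.005) because they play different
roles — readout updates do not feed back into the network state, whereas
recurrent updates reshape the very orbit the readout decodes — and the
model already uses per-matrix trace constants ($f = 1$ vs $f = 0.01$).
The defaults keep them equal: in our experiments asymmetric rates helped
one task while destabilizing another.

Generation reward: $R = L/n$ where $L$ is the length of the longest suffix of the
last $n$ emitted symbols that forms a consecutive run of the target
cycle, so a fully correct window earns 1, a window whose last three
symbols continue the cycle earns $3/n$, and so on. Any rotation of the
cycle counts as correct — the task is cyclic, so there is no distinguished
phase.

### Homeostatic plasticity

Intrinsic plasticity nudges each threshold toward a target rate:
$\Delta\theta_i = \eta_{ip}(s_i - \mu_{ip})$. Recurrent excitatory
neurons share one target $\mu_{ip} \in [0.05, 0.25]$ (default 0.1);
each output neuron's target is the stationary frequency of the symbol it
codes for (for the counting task with $n$ repeats:
$1/(n{+}2),\, n/(n{+}2),\, 1/(n{+}2)$). Inhibitory thresholds are never
adapted. For the winner-take-all readout the per-neuron targets act as an
exploration mechanism: an output that never wins has its threshold
lowered until it wins somewhere, which is what lets reward then decide
*where* it should win.

### Structural plasticity

Once per full-plasticity step, on the excitatory-to-excitatory synapses
only: every existing connection with $w_{ij} < w^{th}$ is pruned
($c_{ij} \to 0$), and every unconnected off-diagonal pair independently
grows a connection with probability $p_{sp}$, initialized at
$w_{new} = 0.001$. Growth candidates are the pairs unconnected before the
call, so a just-pruned pair cannot regrow within the same step. Newborn
connections start with zero eligibility; traces of pruned connections are
cleared.

$p_{sp}$ is the load-bearing calibration of the model: it must be tuned
so that synapse births and deaths balance at a sparse stationary
connection fraction. Death flux comes from reward-driven weight
depression carrying weights below $w^{th}$; when the task is learned
perfectly the neuromodulation factor vanishes, weight motion stops, and
only births remain, so too large a $p_{sp}$ densifies the layer without
bound (with $p_{sp} = 10^{-4}$ the connection fraction climbs from 0.05
past 0.24 within a run and performance collapses). The default
$p_{sp} = 3\times10^{-6}$ (with $w^{th} = 10^{-4}$) keeps the fraction
stationary in the 0.01–0.02 band from sparse starts on the counting
tasks, while still supplying enough growth to rebuild a usable reservoir
from a nearly unconnected start within a training run.

### Two-stage training

Training alternates two stages. Stage 1 (default 100 steps): all rules
active on $W^{EE}$ and $W^{OE}$ — R-STDP, normalization, intrinsic
plasticity of excitatory and output thresholds, structural plasticity.
Stage 2 (default 20,000 steps): the recurrent layer is frozen
bit-exactly (weights, mask, excitatory thresholds) and only the readout
adapts ($W^{OE}$ R-STDP + normalization, output-threshold intrinsic
plasticity); the recurrent eligibility traces are cleared on entry, as
they would decay to zero over the stage anyway. The alternation repeats
200 times by default. Network state, task phase and the reward baseline
carry across all boundaries. For the generation task the emitted symbol
is fed back as the next input throughout training; for the prediction
tasks the true sequence drives the network.

The per-step order within a learning step is: state update → eligibility
update → reward → baseline update → reward-gated weight update → row
normalization → intrinsic plasticity → structural plasticity. The reward
must see the state that produced the prediction; normalization directly
after the weight change maintains the row-sum constraint; structural
plasticity runs last so a newborn weight survives until the next
normalization.

## Evaluation

With plasticity off, `infer()` either presents the true sequence at a
random phase offset (prediction) or seeds one start symbol and feeds
read-outs back (generation). `evaluate_network()` discards a warm-up of
two task periods and reports:

- **overall**: fraction of positions predicted correctly;
- **counting**: fraction of subsequences whose *end-flag transition* —
  the prediction at the $n$-th repeat, whose target is the end flag — is
  correct. This is the only prediction that requires having counted; a
  strict variant (whole subsequence correct) is available via
  `counting_performance(..., strict = TRUE)`;
- **generation**: fraction of emitted symbols that are the cyclic
  successor of their predecessor. Scoring successor validity rather than
  alphabet membership means a constant output stream scores 0, not
  $1/n$.

## Connectivity analyses

The training loop logs every synapse birth and death. From the log the
package computes connection-fraction trajectories, matched
birth-to-death lifecycles (right-censored at the horizon; censored
lifetimes are flagged and excluded from fitting), a maximum-likelihood
lognormal fit of the positive weights (via `fitdistrplus`, with the
Kolmogorov–Smirnov distance as the goodness measure), a discrete
power-law fit of the lifecycle durations (Hurwitz-zeta likelihood,
Clauset-style lower-cutoff selection by minimal KS distance), and a
survival-by-strength table (five weight-quantile bins by default, with
the Spearman rank correlation between bin strength and survival
fraction). `plot_weight_distribution()` and
`plot_lifecycle_distribution()` draw the corresponding log-binned
histogram and log-log complementary CDF with the fitted curves overlaid.

## Synthetic tasks — what they do and do not show

The three benchmarks are exactly periodic symbol streams: counting
$(a\,b^n\,c)^m$, motion $(1\,2\,\cdots\,n)^m$ presented for prediction,
and the same cycle generated autonomously. They probe whether the
recurrent layer can maintain a temporal code (distinguishing the $k$-th
repeat of an identical input) and whether a reward-gated readout can lock
onto it. They contain no noise, no stochastic branching and no
distribution shift; a train/test split is a phase choice, which is why
evaluation starts at a random offset. Passing them shows the plasticity
stack can build and exploit a deterministic temporal code; it does not
show robustness to noisy or aperiodic input.

## Numerical and implementation notes

- The per-step loop is compiled (Rcpp). Binary states let every
  matrix–vector product reduce to sums over the columns of currently
  active neurons, and all recurrent-plasticity passes walk
  column-compressed lists of existing synapses, so stage-1 cost scales
  with the number of synapses, not $N^2$.
- All randomness flows through R's RNG (`set.seed()` reproduces runs
  bit-exactly, including structural plasticity inside the engine). The
  engine draws the number of births from the binomial law over the
  unconnected pairs and places them by rejection sampling —
  distributionally identical to the per-pair Bernoulli formulation used
  by the R-level `structural_step()`.
- Exact threshold ties fire ($\Theta(0) = 1$); readout ties resolve to
  the lowest neuron index; both choices make trajectories reproducible.
- Degenerate inputs are handled explicitly: all-zero afferent rows stay
  zero under normalization; all-equal samples are flagged as degenerate
  by the distribution fits rather than fitted.
- The test suite and the reproduction script scale the protocol down
  (fewer alternations, shorter stage 2, networks of 50–200 neurons) to
  sizes a laptop handles in minutes; the defaults encode the full-scale
  protocol.

## Known limitations

- Convergence of the counting task at large $n$ and $N = 400$ is
  seed-dependent: the reservoir must entrain to the task period, and some
  initializations settle on orbits whose period is a multiple of the task
  period, which caps the counting metric for that run. Averages over
  seeds reflect this variance.
- When a task is learned perfectly the neuromodulation factor is zero and
  synapse death stops while growth continues, so on very long runs the
  connection fraction creeps upward at the birth rate. With the default
  $p_{sp}$ the creep is small on the scale of a training run.
- The model is deterministic given the seed; there is no intrinsic
  neuronal noise. Exploration comes entirely from the homeostatic
  threshold drift and the structural-plasticity randomness.
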