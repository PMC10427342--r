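# sornsp

Self-organizing recurrent spiking networks with structural plasticity.

`sornsp` simulates discrete-time recurrent networks of binary threshold
neurons in which synaptic weights *and* the connection pattern itself are
learned, by the joint action of four biologically motivated plasticity
mechanisms:

- **reward-modulated STDP** — spike-timing coincidences are stored in a
  per-synapse eligibility trace `e` and converted into weight changes only
  when the reward deviates from its running baseline:
  `W(t+1) = W(t) + η (R − b) e`;
- **synaptic normalization** — the afferent weights of every neuron are
  rescaled to sum to 1 after each update, inducing competition;
- **intrinsic plasticity** — thresholds track target firing rates,
  `Δθ = η_ip (s − μ_ip)`;
- **structural plasticity** — unconnected excitatory pairs grow a synapse
  with probability `p_sp` per step (initial weight 0.001) and existing
  synapses whose weight falls below `w_th` are pruned.

The recurrent layer (N excitatory + 0.2 N inhibitory binary neurons) is
trained in a two-stage alternation: a short full-plasticity stage shapes
the recurrent connectivity, then a long stage fine-tunes only the readout
on the frozen reservoir. The package ships the three periodic
sequence-learning benchmarks used to probe the model — counting
`(a b^n c)^m`, motion prediction `(1 2 … n)^m`, and autonomous motion
generation with output-to-input feedback — together with their evaluation
metrics and statistical analyses of the emergent connectivity (lognormal
weight distributions, power-law synapse lifetimes, survival of strong
synapses). The per-step simulation loop is compiled (Rcpp); all runs are
bit-reproducible from a single seed.

Intended for computational-neuroscience work on how multiple plasticity
rules interact to shape recurrent circuits, and as a reference
implementation of a reward-modulated SORN-family model with synapse
growth and pruning.

## Worked example

Train a 200-neuron network on the counting task with n = 4 repeats
(reduced protocol: 50 alternations of 100 full-plasticity steps and
5,000 readout steps) and evaluate it with plasticity frozen:

```r
library(sornsp)

task <- make_counting_sequence(n = 4, m = 10)
config <- sorn_config(n_excitatory = 200, symbols = task$alphabet,
                      p_c = 0.05, seed = 1)
net <- init_network(config)

set.seed(1)
fit <- train(net, task, sorn_protocol(stage1_steps = 100,
                                      stage2_steps = 5000,
                                      alternations = 50))
fit
#> <sorn_training> prediction task, 50 alternations, 255000 steps total
#>   final mean reward (stage 2): 1.000; connection fraction: 0.0590

evaluate_network(fit$network, task, steps = 1000)
#> <eval_report> counting task (n = 4), N = 200, 1000 scored steps
#>   overall    100.00%
#>   counting   100.00%
```

`overall` is the fraction of all next-symbol predictions that are
correct; `counting` is the fraction of subsequences whose end flag — the
prediction that requires having counted the n repeats — is predicted
correctly. The training history (`fit$history`) tracks per-alternation
mean reward and the E–E connection fraction; `fit$events` logs every
synapse birth and death for the connectivity analyses:

```r
lc <- lifecycles(fit$events)
fit_powerlaw(lc$duration[!lc$censored])
fit_lognormal(fit$network$w_ee[fit$network$c_ee == 1])
```

`save_network()` checkpoints a run to a single RDS archive holding the
named elements `config`, the weight matrices (`w_ee`, `c_ee`, `w_ei`,
`w_ie`, `w_oe`), thresholds (`theta_e`, `theta_in`, `theta_o`),
eligibility traces (`e_ee`, `e_oe`), states (`s_e`, `s_in`, `s_o`), the
reward `baseline`, the step counter `t`, the `input_map`, and the R RNG
state, so `load_network()` resumes training bit-exactly.

A thin command-line front end is installed with the package
(`system.file("cli", "sornsp", package = "sornsp")`):

```sh
sornsp train --task counting --n 4 --N 200 --seed 1 --out run.rds
sornsp eval  --checkpoint run.rds --task counting --n 4
sornsp reproduce-table --id table5 --seeds 3
```

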