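# pushpull

Training recurrent spiking neural networks under neocortical constraints,
and measuring the inhibitory circuit motif that task learning produces.

## The problem

Sensory cortex turns spikes into behaviour through sparse, recurrent,
excitatory/inhibitory circuitry. One way to ask *how* is to train a
spiking network that respects the measured constraints — a 4:1 e:i ratio,
class-wise connection probabilities from mouse visual cortex, long-tailed
log-normal synaptic weights, Dale's law, sparse ~20 Hz firing — on a task
animals can do, and then dissect the trained connectivity. This package
implements that entire workflow for a binary motion-entropy
change-detection task: a 4080-ms trial of drifting-dot input at high (15%
coherent) or low (100% coherent) motion entropy, with a possible entropy
change at a random time, reported by the network at every millisecond.

The headline phenomenon the analysis code quantifies is **push-pull
(cross-modulation) inhibition**: after training, inhibitory units send
their strongest weights to units whose firing is modulated by the
*opposite* stimulus label, while excitatory weights concentrate *within* a
label group. The summary statistic is the cross/within-modulation ratio

> mean |weight| between oppositely-modulated units /
> mean |weight| between same-modulated units,

which starts near 1 for both populations (1.06 ± 0.15 for inhibition at
initialisation) and, at full scale, reaches ≈ 2.0 for inhibitory and
≈ 0.6 for excitatory connections after dual (task + rate) training.

## What's inside

| Area | Functions |
| --- | --- |
| Network construction | `network_config()`, `build_network()`, `sample_recurrent_weights()`, `build_io_layers()`, `apply_variant()` |
| ALIF dynamics | `alif_params()`, `alif_step()`, `simulate_trial()`, `readout()` |
| Synthetic task | `channel_profile()`, `make_trial()`, `make_dataset()`, `generate_dot_video()`, `poissonize()` |
| Training | `train_network()`, `batch_update()`, `task_loss()`, `rate_loss()`, `pseudo_derivative()`, `deepr_rewire()` |
| Circuit analysis | `classify_modulation()`, `cross_within_ratio()`, `input_modulation_ratio()`, `top_quantile_persistence()`, `weight_summary()`, `ks_compare()` |
| Perturbation | `jitter_config()`, `jitter_spikes()`, `evaluate_jittered()` |
| Orchestration | `run_pipeline()`, `desk_scale()`, `paper_scale()`, `save_weights()`/`load_weights()` |

The neuron model is an adaptive leaky integrate-and-fire (ALIF) unit:
membrane potential leaking to −70.6 mV with τ = 20 ms, spike threshold
−50.4 mV raised by an adaptation trace (τ = 100 ms, β = 0.16), a 4-ms
refractory period, and current-based synapses at 1-ms resolution.
Training is backpropagation through time over the full 4080-step unroll
with a triangular pseudo-derivative (γ = 0.3) standing in for the spike
discontinuity, Adam on batches of 30 trials, and DEEP R rewiring that
prunes sign-crossing connections and regrows random replacements so the
measured connection densities survive training exactly. The BPTT adjoints
are hand-derived and implemented in compiled C++ (no autodiff); they are
verified against finite differences on a differentiable relaxation of the
same graph. Structural variants reproduce the ablation experiments:
`one_hot` (two-unit readout), `weak_inh` (1.5× instead of 10× inhibition),
`no_dale` (signs free, rewiring off), `no_ee` (recurrent excitation
removed and blocked).

The input videos themselves are replaced by a calibrated 16-channel
Poisson model (the original pipeline's convolutional front-end is out of
scope): each channel fires at a block-constant rate (68-ms blocks) whose
high/low-entropy means differ by that channel's measured rate difference
— 8 channels prefer high entropy, 8 prefer low, mean |difference| 0.021
spikes/ms around a 0.18 spikes/ms baseline.

## Worked example

A reduced ("desk-scale") end-to-end run — build, train on the dual loss,
classify modulation, measure the motif:

```r
library(pushpull)

sc  <- desk_scale(seed = 11)          # 48 e + 12 i units, 1020-ms trials
out <- run_pipeline(sc, out_dir = "snn_run", verbose = TRUE)

read.csv("snn_run/cross_within_ratios.csv")
```

At full scale the protocol is `paper_scale()`: 240 e + 60 i units,
4080-ms trials, 10,000 batch updates of 30 trials (a multi-hour CPU run).

A minimal interactive session:

```r
ws <- build_network(network_config(seed = 1))
set.seed(2)
losses <- sapply(1:20, function(j) {
  tr  <- make_trial(channel_profile(), label_high = j %% 2L)
  sim <- simulate_trial(ws, tr$spikes)   # spike raster + readout
  task_loss(sim$y, rbind(tr$target))
})
mean(losses)
#> [1] 0.4354044
```

An untrained network scores ≈ 0.5 on a balanced trial set: its output
weights cannot yet be driven by the sparse initial activity, so the
readout sits near zero and each trial's mean squared error is roughly its
fraction of '1' timesteps (anywhere from 0 to 1 per trial, 0.5 on
average over many trials). The command-line front-end
(`inst/scripts/snn-pipeline.R`) exposes the same stages as subcommands
(`init`, `dataset`, `train`, `analyze`, `jitter`, `report`) with
`--preset desk|paper`, `--variant`, `--seed`, and `--out-dir` flags.

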