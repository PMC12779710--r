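---
title: "Methods: constrained spiking networks and the push-pull motif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constrained spiking networks and the push-pull motif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pushpull` trains sparse, recurrently connected networks of adaptive leaky
integrate-and-fire (ALIF) units on a binary motion-entropy change-detection
task and quantifies the connectivity motifs that emerge. The default
network has 240 excitatory (e) and 60 inhibitory (i) units (the 4:1
neocortical ratio), connected with class-wise probabilities measured in
mouse visual cortex: p(e→e) = 0.160, p(e→i) = 0.205, p(i→e) = 0.252,
p(i→i) = 0.284. Excitatory synaptic weights are drawn from a long-tailed
log-normal distribution with log-mean −0.64 and log-sd 0.51 (arithmetic
mean `exp(-0.64 + 0.51^2/2)` = 0.6005 mV); inhibitory weights are drawn
from the same distribution, negated and scaled 10× (1.5× in the
weak-inhibition variant). Dale's law — sign-homogeneous outgoing weights
per unit — is enforced throughout training unless the no-Dale variant is
requested.

Each unit carries two hidden states, the membrane potential $v$ and an
adaptation trace $a$. With decay factors $\alpha = e^{-\delta t/\tau_m}$
($\tau_m = 20$ ms) and $\rho = e^{-\delta t/\tau_a}$ ($\tau_a = 100$ ms),
the discrete-time dynamics at 1-ms resolution are

$$v_i^{t+1} = E_m + \alpha\,(v_i^t - E_m) + \sum_{j \ne i} W^{rec}_{ji}
z_j^t + \sum_c W^{in}_{ci} x_c^{t+1} - z_i^t\,(v_{th} - E_m),$$

$$A_i^t = v_{th} + \beta a_i^t, \qquad z_i^t = H(v_i^t - A_i^t), \qquad
a_i^{t+1} = \rho\,a_i^t + z_i^t,$$

with $E_m = -70.6$ mV, $v_{th} = -50.4$ mV, $\beta = 0.16$, a 4-ms
refractory period during which spikes are forced to zero, and membrane
potentials initialised from $\mathcal N(-65, 5^2)$ mV.

**Leak convention.** Printed in isolation, a recurrence of the form
$v^{t+1} = \alpha v^t + \dots$ decays the membrane toward 0 mV, which is
inconsistent with every stated voltage (rest −70.6, threshold −50.4,
initialisation −65). We therefore implement the leak toward $E_m$, the
standard LIF form, and keep the literal decay-toward-zero variant behind
`alif_params(leak_to_rest = FALSE)` for comparison. The post-spike reset
subtracts the constant $v_{th} - E_m = 20.2$ mV, as printed.

## Task and input model

The stimulus is a random-dot kinematogram: 460 dots at 10 px/ms, 1000-ms
lifetimes, with either 100% (low entropy) or 15% (high entropy) of dots
sharing one cardinal direction. Trials last 4080 ms; half contain a single
entropy change at a uniform time in [500, 3500] ms, and the target is the
per-ms binary label of the current entropy level (which label maps to
which level is an experiment-level switch). The dot generator
(`generate_dot_video()`) is included and tested, but the network is driven
by a calibrated 16-channel model of the convolutional front-end that, in
the original pipeline, converted these videos into firing rates.

The channel model assumes a constant underlying rate per 68-ms block (60
blocks per trial). For channel $c$ the entropy-conditional mean rates are
$b_c \pm \delta_c/2$, where $\delta_c$ is the measured high-minus-low rate
difference of that channel (8 positive and 8 negative values, mean
magnitude 0.021 spikes/ms) and the baseline $b_c$ defaults to 0.18
spikes/ms, the measured high-entropy group mean. Block rates are gamma
distributed around these means with a coefficient of variation of 0.45,
chosen once so that the spread of block rates is of the order of the
printed group standard deviations (0.08–0.17 spikes/ms); per-channel
distribution shapes (the measured low-entropy rate distributions are
multimodal) are deliberately not emulated — only the first- and
second-order statistics the recurrent network can exploit. Rates change at
the first block boundary at or after the change time, while the target
flips at the exact millisecond; the 68-ms block grid is part of the input
model, sub-block alignment is not.

Poisson spikes are realised as independent per-ms Bernoulli draws at
rate × dt. Training streams repeat 600 unique trials (shuffled, balanced
counts) to the requested length; batches are consecutive slices of 30
trials.

## Training

The task loss is the per-trial mean squared error between the linear
readout $y^t = \sum_i W^{out}_i z_i^t$ and the binary target, averaged
over all 4080 steps (and over both output units for the one-hot variant).
The rate loss is the squared deviation of the trial's mean population rate
from the 0.020 spikes/ms (20 Hz) target. The total loss is

$$E_{total} = E_{task} + \lambda_{rate} E_{rate}.$$

**Rate-loss scale.** A printed initial rate loss of 0.39 is irreconcilable
with a squared deviation in (spikes/ms)² — a silent network gives exactly
$(0.020)^2 = 4\times10^{-4}$ — so the reference implementation must have
used an unstated scale. We expose $\lambda_{rate}$ as a parameter and
default it to 1250, the value that makes the initial rate-loss
contribution ($1250 \times 4\times10^{-4} = 0.5$) equal in magnitude to
the initial task loss (0.50), which is the only calibration the printed
numbers support. The naive unscaled rate loss is logged alongside every
batch.

Gradients flow through the unrolled 4080-step dynamics by reverse-mode
backpropagation through time. The spike nonlinearity's derivative is
replaced by the pseudo-derivative

$$\psi_i^t = \frac{\gamma_{pd}}{v_{eff}} \max\!\left(0,\; 1 -
\left|\frac{v_i^t - A_i^t}{v_{eff}}\right|\right), \qquad
\gamma_{pd} = 0.3,$$

and $\psi = 0$ during the refractory period. **Normalisation.** Dividing
by the raw threshold $v_{th} = -50.4$ mV would make $\psi$ negative; we
use $v_{eff} = |v_{th} - E_m| = 20.2$ mV, the threshold distance in the
relative-voltage convention standard for this neuron model
(`alif_params(pd_norm = "vth")` switches to $|v_{th}|$).

The adjoint recursion is implemented by hand in compiled code
(`src/snn_core.cpp`); no automatic differentiation is involved. Its
correctness is established by replacing the hard spike with the continuous
pseudo-spike whose exact derivative is $\psi$ (a soft forward mode used
only for verification, with refractoriness disabled so the graph is
differentiable end to end) and checking every weight gradient against
central finite differences on a 5-unit, 10-step toy; agreement is at
1e-4 relative tolerance or better.

Adam is used with lr = 1e-3, $\beta_1$ = 0.9, $\beta_2$ = 0.999,
$\varepsilon$ = 1e-8 (none of these are printed in the reference; these
are the customary defaults, all configurable). Gradients are accumulated
over 30-trial batches; masked (structurally absent) connections receive
zero gradient and never move.

**Rewiring.** After every batch update — the cadence is unstated in the
reference; per-batch is the natural choice given per-batch weight updates
— any active connection whose weight crossed zero or reached exactly zero
is pruned and a replacement is drawn uniformly from the inactive slots of
the same layer and presynaptic sign class, with a fresh weight from the
initial distribution. This conserves per-class connection counts exactly.
Replacement slots never include the diagonal, the blocked e→e block of
the ablation variant, or slots that would let one unit both receive input
and project to the output. When Dale's law is disabled the sign classes
are meaningless and rewiring is skipped entirely; weights may then cross
zero freely (their masks stay fixed).

## Architectural choices the reference leaves open

*Input/output sparsity.* The reference states that input and output
layers are "sparsely connected, matching the statistics of the recurrent
layer" without quantifying them. We treat input channels as excitatory
afferents (connection probability p(e→e) onto e units, p(e→i) onto i
units, uniform weights on [0, 0.4] mV) and reuse p(e→e)/p(i→e) for the
output layer with weights from the recurrent initial distribution.

*Input/output disjointness.* No unit that receives input may project to
the output. With 16 channels at p ≈ 0.16–0.21 essentially every unit
would receive input, leaving no output pool, so the stated rule cannot
hold under unrestricted Bernoulli sampling. We therefore partition units
into an input-eligible half and an output-eligible half (seeded, fraction
configurable via `input_frac`) before per-connection sampling — this
enforces the disjointness while preserving the within-pool densities.

*Population sizes.* The reference abstract mentions 100 i units while its
methods and figures use 60; we adopt 60 (the 4:1 ratio). One figure
caption gives input bounds [0, 2] mV where the methods give [0, 0.4]; we
adopt 0.4, which is consistent with the printed initial input-weight means
near 0.2. Both are configurable.

*Initial recurrent weight scale.* The printed weight-change tables report
initial e→e weights of 0.01 ± 0.03 mV, a factor ~30 below the stated
log-normal mean of 0.6005 mV; the two cannot both describe the same
initialisation (the reference code likely normalised synaptic increments
by a factor of order dt/τ_m). We implement the stated distribution and
equations literally. All modulation-ratio analyses are scale invariant
and unaffected; absolute entries of the weight tables are not reproduced
at face value.

## Analyses

`classify_modulation()` assigns each unit the label (0/1) under which its
pooled evaluation-trial firing rate is higher; silent units and exact ties
stay unclassified and are excluded from all partitions. The evaluation set
is a fixed, seeded collection of held-out trials balanced over the initial
entropy level (60 at full scale; the reference does not state its
evaluation-set size). The same procedure applied to channel spike trains
labels the 16 input channels.

`cross_within_ratio()` reports mean |weight| of across-modulation
connections over mean |weight| of within-modulation connections, per class
and pooled by presynaptic identity. Absolute weights are used throughout:
the reference reports inhibitory ratios above 1 for strengthening negative
weights, so magnitudes are the only consistent reading. Averages run over
active (nonzero) connections only, matching the stated nonzero-weight
convention of the weight-distribution figures. Because unit labels are
fixed identities, ratios are computed retroactively on every stored
epoch snapshot with the final profile.

`top_quantile_persistence()` is rank-based: the fraction of the top-q
connections by initial |weight| still in the top-q by final |weight|. It
is exactly 1 under identity and has expectation q under independent
re-ranking, which the tests verify by permutation.

`jitter_spikes()` displaces every spike independently by an integer offset
uniform on ±5 ms. Offsets that leave the trial or collide with an
occupied millisecond of the same unit are redrawn (bounded retries, then
the nearest free slot), the strictest reading that preserves per-unit
spike counts exactly — the reference asserts unchanged rates but not the
mechanism. Jittered rasters are re-read through the original output
weights without re-simulating the recurrent dynamics, isolating the
timing contribution to the readout.

## Scale presets and problem sizes

`paper_scale()` reproduces the full protocol (300 units, 4080-ms trials,
10,000 batch updates of 30 trials — a multi-hour CPU run).
`desk_scale()` is the package's reduced protocol for interactive use and
the test suite: 48 e + 12 i units, 1020-ms trials (15 blocks of 68 ms)
with the change window scaled to [125, 875] ms, 100 unique trials,
batches of 10, 3000 updates, and lr = 5e-3 — the learning rate is raised
once to compensate for the 5× shorter schedule. At this scale dual
training exhibits the qualitative phenomena (rate control at 20 Hz,
falling task loss, the push-pull direction of the modulation ratios) while
single runs complete in minutes; the full-scale ratio magnitudes
(i ≈ 2.0, e ≈ 0.6) should not be expected from it, and the tests
accordingly check directions and confidence intervals against 1 rather
than the full-scale values.

The two halves of the motif are not equally robust at this scale. The
excitatory within-modulation concentration only requires some units to
become label-selective, and the task-loss decrease only requires the
readout to improve; both appear reliably. The inhibitory cross-modulation
ratio additionally requires *two opposing populations* of modulated units
to form — when a run converges to a nearly unanimous modulation partition
(almost every unit preferring the same label, which small networks often
do), the ratio rests on a handful of connections and is essentially
undefined. Reduced-scale runs should therefore be read as a direction
check with real failure probability, not as a reproduction of the
full-scale effect; the one-hot readout, whose symmetry encourages a
balanced partition, is the more favourable variant for observing the
inhibitory motif at small scale.

## Numerical notes and limitations

- Strict inequality $v > A$ decides a spike; ties do not fire.
- The spike threshold crossing is discontinuous, so training loss curves
  are not strictly monotone batch to batch; the tests compare epoch means.
- Degenerate inputs are handled explicitly: zero connection probabilities
  give empty (valid) layers; `input_w_min = input_w_max = 0` yields a
  network where no unit receives input and every unit is output-eligible;
  an empty output pool is a construction error.
- A network whose units sit exactly at rest has $|v - A| = v_{eff}$ and
  hence zero pseudo-derivative; learning from silence is bootstrapped by
  the membrane-initialisation transient and input drive, and can take a
  few hundred updates to ignite (visible in the rate-only test).
- The generator emulates channel statistics, not videos: conclusions
  about the front-end itself, or about per-channel distribution shapes,
  are out of scope. Passing tests show the recurrent network's behaviour
  under the calibrated channel statistics, not under real dot movies.
- Persistence is HDF5-free: plain-text sparse triplets plus JSON
  sidecars, which round-trip bit-exactly and keep artifacts diffable.
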