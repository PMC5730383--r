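# follownet

Spiking recurrent networks that learn forward models of non-linear
dynamical systems through negative error feedback and a local, online
plasticity rule.

## The problem

Motor control needs a *forward predictive model*: a circuit that, given
the motor command `u(t)` sent to a plant (a muscle–body system, here a
simulated two-link arm or a benchmark oscillator), predicts the plant's
next observable state `x(t)`. `follownet` implements and analyses a
scheme by which a network of heterogeneous spiking neurons can learn such
a model with a rule that is *online* (weights change continuously during
behaviour) and *local* (each synapse combines its own presynaptic trace
with one error signal available in the postsynaptic neuron).

## The model

The reference plant evolves as `dx/dt = h(x, u)`. The network has a
command-representation layer and a recurrent layer of leaky
integrate-and-fire neurons (`tau_m` = 20 ms, threshold 1, refractory
2 ms); spike trains are filtered with the synaptic kernel
`kappa(t) = exp(-t/tau_s)/tau_s`, `tau_s` = 20 ms. The prediction is a
linear readout of filtered recurrent spikes,

    xhat_a(t) = sum_i d_ai (S_i * kappa)(t).

The readout decoders `d` are ridge-regressed so that together with fixed
random error-feedback encoders `e` they form an auto-encoder around the
population. The prediction error `eps = x - xhat` is fed back into every
recurrent neuron with gain `k` = 10, which clamps the output to
`k/(k+1) x` from the start of learning, and the plastic feedforward
(`w_ff`) and recurrent (`w_rec`) weights evolve under the FOLLOW rule

    dw_ij/dt = eta * (I_i^eps * kappa_eps)(t) * (S_j * kappa)(t),
    I_i^eps  = k sum_a e_ia eps_a,

with `kappa_eps` a 200 ms exponential filter. When the error filter is
collapsed onto the synaptic filter, the rule is exactly gradient descent
on the mismatch between each neuron's plastic input current and the
current a realizable solution would inject — the test suite asserts this
identity to machine precision.

Shipped reference systems: a linear decaying oscillator, the van der Pol
oscillator, the chaotic Lorenz system, a linear system behind an odd
cubic input non-linearity, and a two-link planar arm under gravity with
soft joint limits.

## A worked example

Learn the van der Pol oscillator at desk scale (1000 neurons per layer,
500 s of babbling; a few minutes of computation):

```r
library(follownet)
fit <- follow("vanderpol", n_neurons = 1000, t_pre = 4, t_learn = 500,
              t_test = 8, seed = 2)
summary(fit)
#> FOLLOW fit, vanderpol system (1000 neurons/layer)
#>   learning 500 s: block MSE 0.0291 -> 0.00159 (drop factor 18.3)
#>   closed-loop clamp at learning start: |err|/|ref| = 0.115 (1/(k+1) = 0.091)
#>   mean firing rate during learning: 86.6 Hz
#>   open-loop test: mean |err| = 1.56 (reference |x| = 1.13)
```

Reading the numbers: the mean squared error per output dimension,
averaged over 4-s blocks, falls 18-fold over 500 s of closed-loop
learning; from the moment feedback is on, the relative tracking error
sits at the theoretical clamping level `1/(k+1) ~ 0.09`; and in the
open-loop test the network oscillates with the learned orbit but its
phase decorrelates from the chaotic-ish driven reference within a few
hundred milliseconds — at this network size the spiking-noise floor is
amplified by the oscillator's relaxation jumps (see the vignette's
limitations section). Contracting plants track open loop: the same
protocol on `"linear"` gives an open-loop error several times below the
reference amplitude.

Useful methods and experiments:

```r
plot(fit)                                  # 4-s block MSE, log scale
coef(fit)                                  # learned w_ff, w_rec, decoders
predict(fit, input = "ramp_step")          # open-loop test on new input
rp <- realizable_protocol(fit_linear)      # weight recovery vs frozen net
readout_relearn(fit, shuffle = TRUE)       # reservoir-style control
robustness_sweep("connectivity", c(0.25, 1), system = "linear", ...)
tent_map(x3)                               # Lorenz successive-maxima map
```

The full-scale experimental protocols are one call away (hours of compute),
e.g. the low-rate learning-curve/rate-histogram run:

```r
follow("vanderpol", n_neurons = 3000, t_learn = 5000, t_test = 20,
       scheme = "fixed_gain", r2 = 4.5,
       eta_schedule = list(time = 1000, factor = 20))
```

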