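# tdcsnet

Spiking-network simulation of how transcranial direct current stimulation
(tDCS) remodels cortical circuitry through homeostatic structural
plasticity.

tDCS polarizes neuronal membranes by only fractions of a millivolt — far
too weak to fire a quiescent neuron — yet produces aftereffects that
outlast stimulation by hours. `tdcsnet` implements a mechanistic account
of such aftereffects: the stimulated tissue is a recurrent network of
leaky integrate-and-fire (LIF) neurons whose excitatory-to-excitatory
synapses are continuously created and deleted under the control of a
calcium-based firing-rate set point. A weak membrane bias shifts firing
rates, the homeostat responds by rewiring, and the stimulated subpopulation
ends up more densely connected with itself — a cell assembly that persists
after activity has returned to baseline. The package is for computational
neuroscientists who want to simulate, measure, and compare stimulation
protocols (montage, focality, intensity, duty cycle) in this model family.

## The model in brief

Membrane dynamics (current-based LIF with delta synapses):

    tau_m dV_i/dt = -V_i + tau_m * sum_j J_ij S_j(t - d) + dV(t)

with `tau_m` = 10 ms, threshold 20 mV, reset 10 mV, `J_E` = 0.1 mV,
`J_I` = -0.8 mV, 30 kHz external Poisson drive per neuron, and `dV` the
tDCS-induced polarization (applied to excitatory neurons only). Each
excitatory neuron tracks its rate through a calcium trace
`dC/dt = -C/tau_Ca + beta_Ca * S(t)` and grows/removes synaptic elements
by the linear homeostatic rule

    dz/dt = nu * (1 - C / eps)

around the set point `eps`, which corresponds to a target rate of
`eps / (beta_Ca * tau_Ca)` = 8 Hz. Free boutons and spines are randomly
paired into synapses; breaking a synapse frees the partner's element.
Stimulation outcomes are quantified by group firing rates, group-resolved
mean connectivity `Gamma = n^-2 sum_ij A_ij`, and the connectivity time
integral `I_G = sum_k A_k tau_k` of a triple-exponential fit to the
relaxation-phase connectivity change.

## Worked example

Grow a desk-scale network (1,000 excitatory + 250 inhibitory neurons;
full-scale in-degrees, see the vignette) to its homeostatic equilibrium,
then apply the classic uni-group protocol — depolarize 10% of the
excitatory neurons by +0.1 mV for 150 s — and look at what remains after
300 s of relaxation:

```r
library(tdcsnet)

net <- grow_network(network_preset(scale = 0.1),
                    fractions = c(0.1, 0.9), t_grow = 750, seed = 1)
net
#> grown network (1000 E + 250 I), 750 s growth
#>   final E rate 7.89 Hz, mean E-E connectivity 0.8705

exp <- stimulate_network(net, table4_preset("fig2_depol")$schedule, seed = 2)
exp
#> tDCS experiment: uni protocol, 1 cycle(s)
#>   within-G1 connectivity: baseline 0.8757 -> final 0.8743
```

The grown network sits at the 8 Hz set point (`target_rate()`), with the
~0.87 synapses per ordered neuron pair that the inhibition-dominated
balance requires. During stimulation the depolarized group fires above its
set point and *loses* synapses; afterwards it regrows them preferentially
with other stimulated neurons. At the minimal intensity of 0.1 mV that
reallocation is a fraction of a percent — smaller than single-trial
turnover noise in a 100-neuron group block, which is why this run ends a
hair *below* baseline; the package's property tests resolve it by
averaging trials (and the model thereby echoes why such effects are so
hard to measure in practice). At stronger polarization the assembly is
unmistakable in a single run:

```r
strong <- protocol_schedule("uni", c(0.1, 0.9), c(1.2, 0),
                            t_stim = 150, t_relax = 450)
e2 <- stimulate_network(net, strong, seed = 2)
e2
#> tDCS experiment: uni protocol, 1 cycle(s)
#>   within-G1 connectivity: baseline 0.8757 -> final 1.197

relaxation_fit(e2)  # triple-exponential fit from stimulation end
#> exp_fit: I_G = 676.5
#>   A1 = +0.4805, tau1 = 15.68 s
#>   A2 = -1.157, tau2 = 42.7 s
#>   A3 = +0.3991, tau3 = 1800 s
#>   RSS = 0.008475
```

The stimulated 10% end up 37% more densely connected with each other, and
the fitted relaxation decomposes into a fast overshoot and a slow
component whose integral `I_G` summarizes the accumulated outcome.
`e2$rates` holds the windowed group firing rates, `e2$trace` the
connectivity time courses of every group block.

`list_presets()` catalogues the standard montage/duty-cycle
configurations; `sweep_experiment()` tabulates `I_G` over a list of
schedules reusing one grown network. A thin command-line front end is
installed with the package (`exec/tdcsnet`): subcommands `grow`,
`stimulate`, `sweep`, `fit`, `list-presets`.

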