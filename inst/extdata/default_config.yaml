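# Default model configuration.  Every numeric constant of the model lives
# here; nothing is hard-coded in the simulator.  Units: time ms, voltage mV,
# rates Hz, conductances in units of the leak conductance scale below.

dt: 0.1                 # Euler step (ms); refractory period is an exact multiple

neuron:
  C: 1.0                # membrane capacitance (arbitrary units; tau_m = C/g_L = 20 ms)
  g_L: 0.05             # leak conductance
  E_L: -70.0            # leak reversal (mV)
  E_E: 0.0              # excitatory reversal (mV)
  E_I: -80.0            # inhibitory reversal (mV)
  V_th: -55.0           # mean spike threshold (mV)
  V_th_spread: 7.0      # width of the uniform per-neuron threshold spread (mV)
  V_hold: -61.0         # refractory hold voltage (mV)
  t_ref: 2.0            # refractory period (ms)
  sigma_L: 0.1         # std of the multiplicative leak-noise factor (mean 1)

synapse:
  rho: 0.1              # activation increment fraction per presynaptic spike
  tau_T: 80.0           # decay of Timer-cell synaptic activation (ms, slow/NMDA-like)
  tau_M: 30.0           # decay of Messenger-cell synaptic activation (ms)
  tau_I: 10.0           # decay of inhibitory synaptic activation (ms, GABA-like)
  tau_input: 20.0       # decay of feed-forward input channel activation (ms)
  tau_slow: 1400.0      # decay of the slow T -> I_M activation (ms, GABA-B/NMDA-like timescale)
  rho_slow: 0.003       # increment fraction of the slow activation per spike
  tau_gate: 10.0        # decay of the fast T -> I_T gate activation (ms, AMPA-like)
  tau_envelope: 600.0   # decay of the saturating slow envelope trace on T cells (ms)

architecture:
  neurons_per_column: 400   # fixed population size of one functional column
  V_th_offset:          # per-population shifts of the mean threshold (mV)
    IT: -3.0            # I_T gate: releases when the Timer rate falls below its readout level
  V_th_spread_class:    # per-population override of the threshold spread (mV)
    IT: 1.0             # narrow spread: the gate releases sharply
  n_T: 160              # Timer cells
  n_IT: 80              # inhibitory cells associated with Timers
  n_M: 80               # Messenger cells
  n_IM: 80              # inhibitory cells associated with Messengers
  # static connection weights (per-synapse conductance)
  w_T_IT: 4.0e-4        # fast T -> I_T drive (gate readout of the Timer rate)
  w_IT_T: 2.0e-4        # I_T -> T inhibition (weak; the envelope is input-trace paced)
  w_IT_M: 1.5e-2        # I_T -> M gate (strong: M silent while I_T active)
  w_M_IM: 3.0e-3        # M -> I_M (burst recruits the quenching subset)
  w_IM_T: 1.2e-2        # I_M -> T (ramping/burst inhibition terminates Timer activity)
  w_IM_M: 0.0           # I_M -> M (off: I_T alone gates the Messenger burst)
  w_IM_IM: 0.0          # mutual inhibition within I_M (unused by default)
  w_T_M: 0.0            # static part of T -> M (drive is the plastic class)
  w_T_IM_slow: 0.0      # optional slow T -> I_M drive (off: quench is burst-driven)
  w_M_IM_slow: 2.0e-2   # slow M -> I_M drive: the burst arms a persistent hold
  w_lateral_I: 1.0e-4   # I_M -> T of neighbouring columns (lateral inhibition)
  w_M_IT_next: 2.0e-3   # M -> next-column I_T (launch closes the gate like input does)
  # plastic classes: initial values are small and non-zero
  w_TT_init: 1.0e-4     # T -> T recurrent
  w_TM_init: 2.0e-4     # T -> M intra-column
  w_MT_init: 2.0e-5     # M -> next-column T feed-forward
  w_TT_max: 5.0e-3      # non-binding safety ceiling for recurrent weights
  w_TM_max: 3.5e-4      # saturation of the T -> M class
  w_MT_max: 1.5e-3      # saturation of the M -> next-column T class

input:
  n_channels: 40        # Poisson feed-forward channels per column
  rate: 500.0           # channel rate while the stimulus window is open (Hz)
  g_envelope: 2.0e-2    # envelope conductance per T cell at full saturation
  rho_y: 0.003          # envelope increment per incoming channel spike
  rho_y_launch: 0.005   # envelope increment per launch spike (at the MT ceiling)
  duration: 100.0       # stimulus pulse length (ms)
  w_input_T: 2.0e-3     # channel -> T weight
  w_input_IT: 1.0e-3    # channel -> I_T weight

opto:
  N_eff: 0.03           # efficiency constant, fixed across all experiments
  noise_sd: 0.1         # std of the per-neuron per-step noise factor (mean 1)

plasticity:
  tau_p: 350.0          # LTP eligibility-trace decay (ms)
  tau_d: 150.0          # LTD eligibility-trace decay (ms)
  eta_p: 4.0e-4         # LTP trace activation rate (per Hz^2 of Hebbian product)
  eta_d: 6.0e-5         # LTD trace activation rate
  T_p_max: 1.0          # LTP trace saturation
  T_d_max: 2.0          # LTD trace saturation
  tau_rate: 25.0        # exponential filter for pre/post firing rates (ms)
  trace_substeps: 20    # trace/rate updates every this many Euler steps
  consume_on_reward: true  # a reinforcement consumes the traces it converts
  eta: 2.5e-4           # reward learning rate (weight change per unit trace difference)
  n_trials: 100         # training trials
  eta_class:            # per-class multipliers on eta
    TT: 1.0
    TM: 1.0
    MT: 1.0

readout:
  bin: 5.0              # rate histogram bin (ms)
  smooth_sigma: 20.0    # Gaussian smoothing of population rates (ms)
  epileptic_hz: 180.0   # max average M rate above this marks a trial epileptic
  flat_hz: 5.0          # M rate range below this marks a trial flat
  valid_fraction: 0.8   # functional-range validity threshold
  baseline_guard: true  # require peak M rate >= baseline + 1 SD
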