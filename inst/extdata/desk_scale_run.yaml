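# Desk-scale run configuration (field names mirror the model tables);
# read with read_sim_config().
N_E: 1000
N_I: 2500
p_static: 0.1
J_E: 1.0
J_I: -0.8
J_ext: 0.1
r_ext: 30000
delay: 1.0
dt: 0.1
tau_m: 20.0
t_ref: 2.0
V_rest: 0.0
V_reset: 10.0
V_th: 20.0
C_mem: 250
tau_Ca: 10
beta_Ca: 1.0e-4
rule:
  variant: gaussian
  nu: 0.004
  epsilon: 0.0079
  eta: 0.0007
  nu_multiplier: 150
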