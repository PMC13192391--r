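# Example run configuration: calibrated model, 50 ms plateau-inducing step,
# just-threshold IPSG delivered 50 ms after stimulus offset.
parameters:
  gbar_cal: 1.1288379e-3
  gbar_kca: 1.0e-5
protocol:
  duration: 1500
  settle: 2000
  events:
    - kind: step
      onset: 20
      duration: 50
      density: 4.0e-4
    - kind: ipsg
      onset: 120
      g_max: 6.2e-4
      tau_syn: 5
analysis:
  tau_syn: 5
  rel_tol: 0.005
output:
  dir: results
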