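# Synthetic example incubations (generated by the package simulator):
# geometry and tracer metadata keyed by treatment.
default:
  geometry:
    liquid_volume: 0.2
    headspace_volume: 0.05
    subsample_volume: 0.005
    temperature: 27
    salinity: 35
    partition_coefficient: 0.032
  labelling_fraction: 1
treatments:
  DIC:
    labelling_fraction: 0.1
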