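# Example PLS-PM specification: treatment -> soil -> community -> plant,
# mirroring a film-residue field design. Block membership is configurable;
# these manifests match the synthetic demo metadata.
blocks:
  treatment: [treatment]
  soil: [pH, SMC, NH4, NO3, IN, DOC, DON, TC, TN]
  community: [comm_axis1, comm_axis2]
  plant: [biomass, yield]
paths:
  - {from: treatment, to: soil}
  - {from: treatment, to: community}
  - {from: soil, to: community}
  - {from: soil, to: plant}
  - {from: community, to: plant}
modes: A
scheme: path
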