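# Four-layer slab head model, baseline optical and dynamic parameters
# at 785 nm. The last layer is semi-infinite (no thickness entry).
layers:
  - {name: scalp, thickness: 3, mua: 0.019, musp: 0.726, Db: 1.0e-6}
  - {name: skull, thickness: 7, mua: 0.014, musp: 0.946, Db: 8.0e-8}
  - {name: CSF,   thickness: 2, mua: 0.001, musp: 0.002, Db: 1.0e-8}
  - {name: brain,              mua: 0.020, musp: 1.210, Db: 6.0e-6}
g_anisotropy: 0.89
n_tissue: 1.4
wavelength: 785
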