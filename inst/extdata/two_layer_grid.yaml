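# Training-grid specification for the two-layer analytical model.
# Axes may be explicit vectors or {from, to, steps} linear ranges.
brain_mua: [0.005, 0.010, 0.015, 0.020, 0.025]   # 1/mm
brain_musp: [0.9, 1.0, 1.1, 1.2, 1.3]            # 1/mm
thickness: [8, 9, 10, 11, 12, 13, 14, 15]        # mm, extracerebral layer
Db_brain: {from: 5.0e-7, to: 5.0e-5, steps: 100}  # mm^2/s
fraction: {from: 0.05, to: 0.3, steps: 20}        # Db_extra = fraction * Db_brain
fixed:
  extra_mua: 0.019    # 1/mm
  extra_musp: 0.86    # 1/mm
  rho: 35             # mm
  beta: 0.5
  wavelength: 785     # nm
  n0: 1.4
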