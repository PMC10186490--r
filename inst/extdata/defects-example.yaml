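# Example defect specification for `printfid simulate --defects`.
# Magnitudes in mm; see ?defect_spec.
swell_mm: 0.2
blob_radius_mm: 1.5
blob_sites: 4
ooze_width_mm: 0.8
n_ooze: 2
shift_mm: [0.5, -0.3]
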