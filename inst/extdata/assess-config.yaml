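# Example pipeline configuration for `printfid assess --config`.
grid_px: 9          # localization grid size (px)
sigma_grid: 2       # heatmap smoothing sigma (grid units)
registration: xcorr # or "com" (centre of mass)
max_shift: 100      # registration search radius (px)
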