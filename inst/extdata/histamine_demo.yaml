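# Example analysis configuration: histamine-style time lapse at 32 nm/px.
# Any key omitted falls back to the package default.
pixel_size: 32          # nm per pixel (50 px = 1.6 um)
window_diameter: 50     # background sliding-window diameter, px
masks:
  erode_iters: 1        # core (cristae proxy)
  dilate_iters: 2       # outer rim boundary (IBM proxy)
profile_width: 50       # cross-section averaging width, px
connectivity: 8
min_area_px: 4
delta_sign: tmrm_minus_mtg
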