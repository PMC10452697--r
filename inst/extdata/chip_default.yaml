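# Default chamber-array dPCR chip: 54 channels, 108 rows x 198 chambers
# (21,384 chambers of ~0.71 nL). Pitch is a rendering parameter only.
layout:
  n_channels: 54
  n_rows: 108
  chambers_per_row: 198
  chamber_diameter: 87      # um
  chamber_height: 120       # um
  channel_width: 60         # um
  channel_height: 55        # um
  pitch_x: 110              # um
  pitch_y: 110              # um
panel:
  channels: [Cy5, FAM, HEX, ROX]
  reference_channel: Cy5
  target_map:
    G12S: FAM
    G12C: HEX
    G12R: ROX
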