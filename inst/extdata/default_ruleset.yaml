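fad_pattern: GxGxx[GAN]
fmo_core_pattern: FxGxxxHxxx
fmo_extra_positions: 2
nadph_pattern: Gx[GN]xx[GA]
fad_window:
- 0
- 250
spacing_fad_fmo:
- 150
- 220
spacing_fmo_nadph:
- 0
- 40
spacing_fad_nadph:
- 150
- 280
nmo_window:
- -46
- -9
nmo_flank:
- 6
- 4
allow_mismatch: yes
diagnostic_penultimate:
- H
- 'Y'
- F
- W
diagnostic_last:
- P
- K
- R
extension_min: 100
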