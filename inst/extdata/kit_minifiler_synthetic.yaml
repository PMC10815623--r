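# Synthetic two-analysis-dye demonstration kit (plus ILS channel).
# Positions and allele bins are invented; they match no commercial kit.
kit_name: MiniSynth-2
dyes: [B, G, O]
read_region: [80, 480]
ils_fragments: [80, 120, 160, 200, 240, 280, 320, 360, 400, 440, 480]
markers:
  - name: M1
    dye: B
    range: [100, 140]
    repeat_bp: 4
    alleles: {"8": 103.0, "9": 107.0, "10": 111.0, "11": 115.0, "12": 119.0, "13": 123.0}
  - name: M2
    dye: B
    range: [150, 190]
    repeat_bp: 4
    alleles: {"6": 153.0, "7": 157.0, "8": 161.0, "9": 165.0, "10": 169.0}
  - name: M3
    dye: G
    range: [100, 140]
    repeat_bp: 4
    alleles: {"8": 104.0, "9": 108.0, "10": 112.0, "11": 116.0, "12": 120.0}
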