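# Desk-scale demonstration run: 2 subjects on the small 6-community atlas,
# regional masks from the atlas community tags, 99 permutations.
seed: 1
synthetic:
  n_subjects: 2
  atlas: demo
hubs:
  n_perm: 99
roi:
  source: labels
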