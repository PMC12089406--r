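# Atom-name -> site-label maps for the diketopiperazine pathway
# substrates as emitted by build_dkp().  Adapt (or supply your own map)
# for deposited structures whose substrate atom names differ.
substrate_1:
  "C7": "C-7"
  "C2'": "C-2'"
  "C5A": "C-5a"
  "C6": "C-6"
substrate_2:
  "C2'": "C-2'"
  "C3'": "C-3'"
  "C5": "C-5"
substrate_3:
  "C3'": "C-3'"
  "C5": "C-5"
  "C6": "C-6"
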