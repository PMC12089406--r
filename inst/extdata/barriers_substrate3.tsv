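# Hydrogen-abstraction activation free energies (kcal/mol) for the
# pathway substrate 3 against the truncated Fe(IV)-oxo theozyme.
# Only the text-documented value is shipped; barriers for the remaining
# sites must be transcribed by the user before use.
C-5	5.3
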