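# Localization term dictionaries, applied in priority order:
# secreted tier first, then plasma-membrane tier; everything else is
# intracellular. Matching is case-insensitive on whole terms.
version: 1
secreted_terms:
  - secreted
  - extracellular region
  - extracellular space
  - extracellular matrix
membrane_terms:
  - plasma membrane
  - cell membrane
  - cell junction
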