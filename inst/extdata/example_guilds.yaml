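# Example functional-guild definition file (rank-level patterns).
# Same structure as write_guild_definitions() output; replace labels to
# match your survey's guild table.
AOB:
- rank: family
  label: Nitrosomonadaceae
- rank: genus
  label: Nitrosomonas
NOB:
- rank: genus
  label: Nitrospira
- rank: genus
  label: Nitrotoga
PAO:
- rank: genus
  label: Candidatus Accumulibacter
- rank: genus
  label: Tetrasphaera
BFB:
- rank: genus
  label: Gordonia
- rank: genus
  label: Thiothrix
anammox:
- rank: genus
  label: Candidatus Brocadia
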