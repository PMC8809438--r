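# Geographical-origin categories grouped into supergroups.
# Editable: any category -> supergroup map with the literal category
# "Unknown" reserved for the Unknown supergroup.
Laurasian:
  - Eastern Asia
  - Tethyan
  - North America
  - Southwest Asia
  - Central Asia
  - Eurasia
  - Southwest China
  - Northwest China
  - Qinghai-Tibet plateau
  - Eastern Asia or Western North America
  - Central Asia or the Qinghai-Tibet plateau
  - Northern Hemisphere unknown
Gondwanan:
  - Africa
  - Southern Hemisphere unknown
Unknown:
  - Unknown
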