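# Model configuration for the reduced (synthetic) nitrogen-metabolism core
# model of Chlamydomonas reinhardtii night-time metabolism.
# External metabolites are buffered: carbon sources (G6P from starch
# breakdown, acetate), the three nitrogen sources, CO2 and the five target
# amino acids.
external:
  - G6P
  - ACE
  - NO3
  - NO2
  - NH4
  - CO2
  - GLY
  - ALA
  - ASN
  - LYS
  - ARG
carbon_sources:
  - G6P
  - ACE
targets:
  - GLY
  - ALA
  - ASN
  - LYS
  - ARG
# Reactions whose enzymes are encoded by (UG)7-repeat-bearing mRNAs, i.e.
# presumed under CHLAMY1 control: glucose-6-phosphate isomerase, the
# NADP-dependent isocitrate dehydrogenase variant, nitrite reductase and
# argininosuccinate lyase (the set is overridable at run time).
regulated_reactions:
  - R_PGI
  - R_IDHNADP
  - R_NIR
  - R_ASL
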