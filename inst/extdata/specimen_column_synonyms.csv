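canonical,synonym
specimen,ID
specimen,Specimen
specimen,specimen_id
species,Species
population,Population
hive,Hive
hive,Colony
hive,colony
AL,AL (mm3)
MB,MB (mm3)
CX,CX (mm3)
ME,ME (mm3)
LO,LO (mm3)
OTH,OTH (mm3)
OL,OL (mm3)
total,Total
total,Total brain
total,Total brain volume
total,Brain
AL_left,AL left
AL_right,AL right
MB_left,MB left
MB_right,MB right
ME_left,ME left
ME_right,ME right
LO_left,LO left
LO_right,LO right
OL_left,OL left
OL_right,OL right
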