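LIPITOR	ATORVASTATIN
ATORVASTATIN	ATORVASTATIN
ATORVASTATIN CALCIUM	ATORVASTATIN
HUMIRA	ADALIMUMAB
ADALIMUMAB	ADALIMUMAB
AUGMENTIN	AMOXICILLIN|CLAVULANIC ACID
AMOXICILLIN CLAVULANATE	AMOXICILLIN|CLAVULANIC ACID
AMOXICILLIN	AMOXICILLIN
REVLIMID	LENALIDOMIDE
LENALIDOMIDE	LENALIDOMIDE
DUPIXENT	DUPILUMAB
DUPILUMAB	DUPILUMAB
UNKNOWN HERBAL BLEND	UNRESOLVABLE
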