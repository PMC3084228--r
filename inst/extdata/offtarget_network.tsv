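source	target	sign	source_kind	target_kind
EGFR	PI3K	activation	off_target	intermediate
EGFR	Ras	activation	off_target	intermediate
IGF1R	PI3K	activation	off_target	intermediate
FAK	PI3K	activation	off_target	intermediate
Abl	Ras	activation	off_target	intermediate
FGFR	PI3K	activation	off_target	intermediate
FGFR	Ras	activation	off_target	intermediate
EPHB4	PI3K	activation	off_target	intermediate
ARK	MAPK	activation	off_target	pathway
ARK	mTOR	activation	off_target	pathway
PDK1	Akt	activation	off_target	intermediate
Akt2	PI3K_Akt	activation	off_target	pathway
CDK2	Cell_proliferation	dual	off_target	effect
PI3K	PIP3	activation	intermediate	intermediate
PIP3	Akt	activation	intermediate	intermediate
Akt	PI3K_Akt	activation	intermediate	pathway
Akt	NFkB	activation	intermediate	pathway
Akt	mTOR	activation	intermediate	pathway
Akt	Glucose_uptake	activation	intermediate	pathway
Akt	Glycogenolysis	dual	intermediate	pathway
Ras	MAPK	activation	intermediate	pathway
Ras	JNK	activation	intermediate	pathway
PI3K_Akt	Cell_survival	activation	pathway	effect
PI3K_Akt	Apoptosis	inhibition	pathway	effect
MAPK	Cell_proliferation	activation	pathway	effect
JNK	Cell_proliferation	activation	pathway	effect
NFkB	Cell_survival	activation	pathway	effect
mTOR	Cell_proliferation	activation	pathway	effect
Glucose_uptake	Insulin_resistance	inhibition	pathway	effect
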