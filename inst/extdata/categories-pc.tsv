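type	category
Conversion	SIMPLE
Phosphorylation	SIMPLE
Dephosphorylation	SIMPLE
Acetylation	SIMPLE
Deacetylation	SIMPLE
Methylation	SIMPLE
Demethylation	SIMPLE
Ubiquitination	SIMPLE
Deubiquitination	SIMPLE
Hydroxylation	SIMPLE
Dehydroxylation	SIMPLE
Localization	SIMPLE
Transport	SIMPLE
Gene_expression	SIMPLE
Transcription	SIMPLE
Translation	SIMPLE
Degradation	SIMPLE
Binding	NON-REG
Dissociation	NON-REG
Pathway	NON-REG
Regulation	REGULAT
Positive_regulation	REGULAT
Negative_regulation	REGULAT
Activation	REGULAT
Inactivation	REGULAT
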