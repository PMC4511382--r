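# Pathway Curation task configuration: refined entity generalisation.
# Gene_or_gene_product and Complex collapse into PROTEIN (following the
# reference resources of the task's entity definitions); Simple_chemical and
# Cellular_component keep their own labels.

GOLD
Simple_chemical
Gene_or_gene_product
Complex
Cellular_component

PREDICTION
Conversion
Phosphorylation
Dephosphorylation
Acetylation
Deacetylation
Methylation
Demethylation
Ubiquitination
Deubiquitination
Hydroxylation
Dehydroxylation
Localization
Transport
Gene_expression
Transcription
Translation
Degradation
Binding
Dissociation
Regulation
Positive_regulation
Negative_regulation
Activation
Inactivation
Pathway

TRIGGERS
Conversion
Phosphorylation
Dephosphorylation
Acetylation
Deacetylation
Methylation
Demethylation
Ubiquitination
Deubiquitination
Hydroxylation
Dehydroxylation
Localization
Transport
Gene_expression
Transcription
Translation
Degradation
Binding
Dissociation
Regulation
Positive_regulation
Negative_regulation
Activation
Inactivation
Pathway

ROLES
Theme
Theme2
Cause
Participant
Participant2
Site
FromLoc
ToLoc
Product
Product2

LABEL_GENERALISATIONS
Positive_regulation -> REGULATION
Regulation -> REGULATION
Negative_regulation -> REGULATION
Phosphorylation -> PTM
Dephosphorylation -> PTM
Acetylation -> PTM
Deacetylation -> PTM
Methylation -> PTM
Demethylation -> PTM
Ubiquitination -> PTM
Deubiquitination -> PTM
Hydroxylation -> PTM
Dehydroxylation -> PTM
@events -> EVENT
Gene_or_gene_product -> PROTEIN
Complex -> PROTEIN

INSTANCE_RULES
Regulation, Positive_regulation, Negative_regulation

OPTIONS
C = 1
hashBits = 20
mode = combined
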