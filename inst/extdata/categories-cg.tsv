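type	category
Development	ANATOMY
Blood_vessel_development	ANATOMY
Growth	ANATOMY
Death	ANATOMY
Cell_death	ANATOMY
Breakdown	ANATOMY
Cell_proliferation	ANATOMY
Cell_division	ANATOMY
Cell_differentiation	ANATOMY
Remodeling	ANATOMY
Reproduction	ANATOMY
Mutation	PATHOL
Carcinogenesis	PATHOL
Cell_transformation	PATHOL
Metastasis	PATHOL
Infection	PATHOL
Metabolism	MOLECUL
Synthesis	MOLECUL
Catabolism	MOLECUL
Amino_acid_catabolism	MOLECUL
Glycolysis	MOLECUL
Phosphorylation	MOLECUL
Dephosphorylation	MOLECUL
DNA_methylation	MOLECUL
DNA_demethylation	MOLECUL
Acetylation	MOLECUL
Deacetylation	MOLECUL
Glycosylation	MOLECUL
Ubiquitination	MOLECUL
Gene_expression	GENERAL
Transcription	GENERAL
Translation	GENERAL
Protein_processing	GENERAL
Localization	GENERAL
Binding	GENERAL
Dissociation	GENERAL
Regulation	REGULAT
Positive_regulation	REGULAT
Negative_regulation	REGULAT
Pathway	REGULAT
Planned_process	PLANNED
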