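# Cancer Genetics task configuration: refined entity generalisation.
# Entities are collapsed into the three general groups of the task's entity
# hierarchy (anatomical, pathological, molecular) instead of one ENTITY.

GOLD
Organism
Organism_subdivision
Anatomical_system
Organ
Multi-tissue_structure
Tissue
Developing_anatomical_structure
Cell
Cellular_component
Organism_substance
Immaterial_anatomical_entity
Gene_or_gene_product
Simple_chemical
Protein_domain_or_region
Amino_acid
DNA_domain_or_region
Pathological_formation
Cancer

PREDICTION
Development
Blood_vessel_development
Growth
Death
Cell_death
Breakdown
Cell_proliferation
Cell_division
Cell_differentiation
Remodeling
Reproduction
Mutation
Carcinogenesis
Cell_transformation
Metastasis
Infection
Metabolism
Synthesis
Catabolism
Amino_acid_catabolism
Glycolysis
Gene_expression
Transcription
Translation
Protein_processing
Phosphorylation
Dephosphorylation
DNA_methylation
DNA_demethylation
Acetylation
Deacetylation
Glycosylation
Ubiquitination
Localization
Binding
Dissociation
Regulation
Positive_regulation
Negative_regulation
Planned_process
Pathway

TRIGGERS
Development
Blood_vessel_development
Growth
Death
Cell_death
Breakdown
Cell_proliferation
Cell_division
Cell_differentiation
Remodeling
Reproduction
Mutation
Carcinogenesis
Cell_transformation
Metastasis
Infection
Metabolism
Synthesis
Catabolism
Amino_acid_catabolism
Glycolysis
Gene_expression
Transcription
Translation
Protein_processing
Phosphorylation
Dephosphorylation
DNA_methylation
DNA_demethylation
Acetylation
Deacetylation
Glycosylation
Ubiquitination
Localization
Binding
Dissociation
Regulation
Positive_regulation
Negative_regulation
Planned_process
Pathway

ROLES
Theme
Theme2
Cause
Participant
Participant2
Site
Site2
AtLoc
ToLoc
FromLoc
Instrument
Instrument2

LABEL_GENERALISATIONS
Positive_regulation -> REGULATION
Regulation -> REGULATION
Negative_regulation -> REGULATION
Phosphorylation -> PTM
Dephosphorylation -> PTM
DNA_methylation -> PTM
DNA_demethylation -> PTM
Acetylation -> PTM
Deacetylation -> PTM
Glycosylation -> PTM
Ubiquitination -> PTM
@events -> EVENT
Organism -> ANATOMICAL
Organism_subdivision -> ANATOMICAL
Anatomical_system -> ANATOMICAL
Organ -> ANATOMICAL
Multi-tissue_structure -> ANATOMICAL
Tissue -> ANATOMICAL
Developing_anatomical_structure -> ANATOMICAL
Cell -> ANATOMICAL
Cellular_component -> ANATOMICAL
Organism_substance -> ANATOMICAL
Immaterial_anatomical_entity -> ANATOMICAL
Gene_or_gene_product -> MOLECULAR
Simple_chemical -> MOLECULAR
Protein_domain_or_region -> MOLECULAR
Amino_acid -> MOLECULAR
DNA_domain_or_region -> MOLECULAR
Pathological_formation -> PATHOLOGICAL
Cancer -> PATHOLOGICAL

INSTANCE_RULES
Regulation, Positive_regulation, Negative_regulation

OPTIONS
C = 1
hashBits = 20
mode = combined
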