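pathway_id	category
Transport reactions	Miscellaneous
P01_essential_biosynthesis	Amino acid metabolism
P02_unique_export	Carbohydrate metabolism
P03_internal_cycle	Lipid metabolism
P04_redundant_route	Nucleotide metabolism
P05_redundant_route	Nucleotide metabolism
P06_dead_end	Lipid metabolism
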