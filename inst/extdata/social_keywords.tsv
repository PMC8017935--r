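class	keyword
biofilm	biofilm
biofilm	extracellular polysaccharide
biofilm	cell adhesion
biofilm	cell aggregation
quorum_sensing	quorum sensing
quorum_sensing	autoinducer
secretion_systems	secretion system
siderophores	siderophore
siderophores	enterobactin
siderophores	pyoverdine
siderophores	iron chelate
antibiotic_degradation	antibiotic catabolic
antibiotic_degradation	beta-lactamase
antibiotic_degradation	response to antibiotic
antibiotic_degradation	penicillin catabolic
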