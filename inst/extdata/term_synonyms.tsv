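raw_term	curated_term
Quiescent	Quiescent
Quiescent/Low	Quiescent
Low signal	Quiescent
Dead	Quiescent
Low	Quiescent
Empty	Quiescent
Heterochromatin	ConstitutiveHet
Constitutive heterochromatin	ConstitutiveHet
Heterochromatin;low signal	ConstitutiveHet
ZNF genes & repeats	ConstitutiveHet
H3K9me3 repressed	ConstitutiveHet
Facultative heterochromatin	FacultativeHet
Polycomb repressed region	FacultativeHet
Polycomb repressed	FacultativeHet
Repressed Polycomb	FacultativeHet
Weak Repressed Polycomb	FacultativeHet
Repressed	FacultativeHet
Transcription	Transcribed
Transcribed	Transcribed
Weak transcription	Transcribed
Strong transcription	Transcribed
Transcription elongation	Transcribed
Transcription transition	Transcribed
Gene body	Transcribed
Promoter	Promoter
Active Promoter	Promoter
Active TSS	Promoter
TSS	Promoter
Flanking Active TSS	Promoter
Poised Promoter	Bivalent
Bivalent/Poised TSS	Bivalent
Bivalent TSS	Bivalent
Bivalent Enhancer	Bivalent
Bivalent	Bivalent
Poised	Bivalent
Enhancer	Enhancer
Strong Enhancer	Enhancer
Active Enhancer	Enhancer
Candidate enhancer	Enhancer
Weak Enhancer	RegPermissive
Weak enhancer	RegPermissive
Promoter flanking	RegPermissive
Flanking region	RegPermissive
Permissive regulatory region	RegPermissive
Regulatory Permissive	RegPermissive
Artifact	Unclassified
Insulator	Unclassified
CTCF	Unclassified
Genic enhancer	Unclassified
FAIRE	Unclassified
Unclassified	Unclassified
Unknown	Unclassified
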