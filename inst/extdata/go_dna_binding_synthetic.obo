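format-version: 1.2
ontology: go-dna-binding-synthetic
! Synthetic, heavily reduced molecular-function subtree for testing and for
! the bundled data generator. Term ids follow GO conventions but the subtree
! is NOT the full Gene Ontology.

[Term]
id: GO:0003674
name: molecular_function

[Term]
id: GO:0005488
name: binding
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0003676
name: nucleic acid binding
is_a: GO:0005488 ! binding

[Term]
id: GO:0003677
name: DNA binding
is_a: GO:0003676 ! nucleic acid binding

[Term]
id: GO:0043565
name: sequence-specific DNA binding
is_a: GO:0003677 ! DNA binding

[Term]
id: GO:0003690
name: double-stranded DNA binding
is_a: GO:0003677 ! DNA binding

[Term]
id: GO:0000976
name: transcription regulatory region sequence-specific DNA binding
is_a: GO:0043565 ! sequence-specific DNA binding

[Term]
id: GO:0003700
name: DNA-binding transcription factor activity
is_a: GO:0043565 ! sequence-specific DNA binding

[Term]
id: GO:0003723
name: RNA binding
is_a: GO:0003676 ! nucleic acid binding

[Term]
id: GO:0016301
name: kinase activity
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0005515
name: protein binding
is_a: GO:0005488 ! binding

[Typedef]
id: part_of
name: part of
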