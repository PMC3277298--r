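label	display_name	clade
C_sp1	C. sp. 1	basal
C_plicata	C. plicata	basal
C_elegans	C. elegans	Elegans group
C_briggsae	C. briggsae	Elegans group
C_sp9	C. sp. 9	Elegans group
C_sp5	C. sp. 5	Elegans group
C_remanei	C. remanei	Elegans group
C_brenneri	C. brenneri	Elegans group
C_sp10	C. sp. 10	Elegans group
C_sp11	C. sp. 11	Elegans group
C_sp16	C. sp. 16	Elegans group
C_sp15	C. sp. 15	Elegans super-group
C_japonica	C. japonica	Japonica group
C_sp7	C. sp. 7	Japonica group
C_sp14	C. sp. 14	Japonica group
C_sp17	C. sp. 17	Japonica group
C_sp18	C. sp. 18	Japonica group
C_sp19	C. sp. 19	Japonica group
C_sp20	C. sp. 20	Drosophilae super-group
C_sp6	C. sp. 6	Drosophilae super-group
C_sp13	C. sp. 13	Drosophilae super-group
C_drosophilae	C. drosophilae	Drosophilae group
C_sp2	C. sp. 2	Drosophilae group
C_angaria	C. angaria	Angaria group
C_sp8	C. sp. 8	Angaria group
C_sp12	C. sp. 12	Angaria group
Protorhabditis_sp	Protorhabditis sp. (outgroup)	outgroup
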