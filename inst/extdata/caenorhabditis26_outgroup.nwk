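(Protorhabditis_sp,(C_sp1,(C_plicata,(((C_elegans,((C_remanei,(C_sp5,(C_briggsae,C_sp9))),((C_brenneri,C_sp10),(C_sp11,C_sp16)))),(C_sp15,((C_japonica,C_sp14),(C_sp7,(C_sp17,(C_sp18,C_sp19)))))),(C_sp20,((C_sp6,C_sp13),((C_drosophilae,C_sp2),(C_sp8,(C_angaria,C_sp12)))))))));
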