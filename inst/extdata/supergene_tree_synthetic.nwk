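(((Sh_haplotype:0.1,Sp_haplotype:0.1):3.8,P_subnitidus:3.9):1.0,P_outgroup:4.9);
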