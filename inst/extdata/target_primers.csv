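target,forward_seq,reverse_seq,amplicon_length
TECTA,AGTTCTCCTACACCCTCCTG,TGCCTCCTATCTTGACCTCC,147
OTOF,TCCTCAACCCTCTCAAGTCC,AGCTTTTTGACCATGTAGCC,168
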