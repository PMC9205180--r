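>IGHM_CH1_BALB|segment=C|strain=BALB|note=printed_table2;rs29176517g_at_pos292
gagagtcagtccttcccaaatgtcttccccctcgtctcctgcgagagcccctgtctgataagaatctggtggccatgggctgcctggcccgggacttcctgcccagcaccatttccttcacctggaactaccagaacaacactgaagtcatccagggtatcagaaccttcccaacactgaggacagggggcaagtacctagccacctcgcaggtgttgctgtctcccaagagcatccttgaaggttcagatgaatacctggtatgcaaaatccactacggaggcaaaaacagagatctgcatgtgcccattcca
>IGHM_CH1_B6|segment=C|strain=B6|note=derived_single_snp;BALB_CH1_with_g292a;printed_B6_form_carries_an_extra_c_in_a_homopolymer_treated_as_transcription_artifact
gagagtcagtccttcccaaatgtcttccccctcgtctcctgcgagagcccctgtctgataagaatctggtggccatgggctgcctggcccgggacttcctgcccagcaccatttccttcacctggaactaccagaacaacactgaagtcatccagggtatcagaaccttcccaacactgaggacagggggcaagtacctagccacctcgcaggtgttgctgtctcccaagagcatccttgaaggttcagatgaatacctggtatgcaaaatccactacggaggcaaaaacaaagatctgcatgtgcccattcca
>IGHG2B_CH1_BALB|segment=C|strain=BALB|note=printed_table2;rs45969375c;snp_offset_placement_synthetic_pos100
gccaaaacaacacccccatcagtctatccactggcccctgggtgtggagatacaactggttcctccgtgactctgggatgcctggtcaagggctacttccctgagtcagtgactgtgacttggaactctggatccctgtccagcagtgtgcacaccttcccagctctcctgcagtctggactctacactatgagcagctcagtgactgtcccctccagcacctggccaagtcagaccgtcacctgcagcgttgctcacccagccagcagcaccacggtggacaaaaaactt
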