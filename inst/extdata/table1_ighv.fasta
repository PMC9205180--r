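>balbIGHV036|segment=V|strain=BALB|functionality=functional|provenance=reported|note=printed_table1;also_reported_by_Corcoran_et_al
caggttactctgaaagagtctggccctgggatattgcagccatcacagacgcttagcctggcctgtactttctctgggatttcactgagtacttctggtatgggtttgagctggcttcgtaagccctcagggaaggctttagagtggctggcaagcatttggaataatgataactactacaacccatctttgaagagccggctcacaatctccaaggagacctccaacaaccaagtattccttaaactcaccagtgtggacactgcagattctgccacatactactgtgcttggagagag
>balbIGHV037|segment=V|strain=BALB|functionality=functional|provenance=reported|note=printed_table1;3prime_variant_of_balbIGHV027
caagttactctaaaagagtctggccctgggatattgaagccctcacagaccctcagtctgacttgttctttctctgggttttcactgagcacttctggtatgggtgtaggctggattcgtcagccttcagggaagggtctggagtggctggcacacatttggtgggatgatgataagtactataacccatccctgaagagccagctcacaatctccaaggatacctccagaaaccaggtattcctcaagatcaccagtgtggacactgcagatactgccacttactactgtgctcgaagag
>balbIGHV038|segment=V|strain=BALB|functionality=functional|provenance=reported|note=printed_table1;balbIGHV009_G32A
aaggtccagctgcagcagtctggagctgagctggtgaaacccggggcatcagtgaagctgtcctgcaaggcttctggctacaccttcactgagtatattatacactgggtaaagcagaggtctggacagggtcttgagtggattgggtggttttaccctggaagtggtagtataaagtacaatgagaaattcaaggacaaggccacattgactgcggacaaatcctccagcacagtctatatggagcttagtagattgacatctgaagactctgcggtctatttctgtgcaagacacgaaga
>balbIGHV039|segment=V|strain=BALB|functionality=pseudogene|provenance=reported|note=printed_table1;musIGHV398_variant;footnote_says_7_missing_nt_but_printed_gap_run_has_9_dashes;dash_free_sequence_stored
gaggtccagctgcaacagtctggacctgagctggtgaagcctggagcttcaatgaagatatcctgcaaggctactcattcactggctacaccatgaactgggtgaagcagagccatggaaagaaccttgagtggattggacttattaatccttacaatggtggtactagctacaaccagaagttcaagggcaaggccacattaactgtagacaagtcatccagcacagcctacatggagctcctcagtctgacatctgaggactctgcagtctattactgt
>b6IGHV040|segment=V|strain=B6|functionality=pseudogene|provenance=extended|ext5=27|ext3=3|note=printed_table1;musIGHV269_full_length;three_bases_lost_in_source_transcription_restored_as_nnn_after_pos_76
caggttcagctccagcagtctgggcctgagctggcaaggccttgggcttcagtgaagatatcctgccaggctttctnnnacaccttttccagaagggtgcactttgccattagggataccaactactggatgcagtgggtaaaacagaggcctggacagggtctggaatggatcggggctatttatcctggaaatggtgatactagttacaatcagaagttcaagggcaaggccacattgactgcagacaaatcctccagcacagcctacatgcaactcagcagcctgacatctgaggactctgcggtctattactgtgcatga
>balbIGHV041|segment=V|strain=BALB|functionality=pseudogene|provenance=inferred|note=printed_table1;C100T_variant_of_b6IGHV040;three_bases_lost_in_source_transcription_restored_as_nnn_after_pos_76
caggttcagctccagcagtctgggcctgagctggcaaggccttgggcttcagtgaagatatcctgccaggctttctnnnacaccttttccagaagggtgtactttgccattagggataccaactactggatgcagtgggtaaaacagaggcctggacagggtctggaatggatcggggctatttatcctggaaatggtgatactagttacaatcagaagttcaagggcaaggccacattgactgcagacaaatcctccagcacagcctacatgcaactcagcagcctgacatctgaggactctgcggtctattactgtgcatga
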