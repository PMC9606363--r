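# Example pipeline configuration. The reference exon and primer pair
# below are SYNTHETIC placeholders shipped for tests and examples;
# analyses of real data must substitute the genuine sequences.
reference_exon: GAAAGTGATCTAATTTACGCCGGATGCCTTTCTAGGATAGCGCGGCCCGTAGGAATCACGTATCGGTCTACATTAGACACCAGTCCGGCATGCTGCGTGATATCATCGGACTTCATTCGATTGTCTAGTGATGAATCTATCCCGATAGATAGTTGTTGGCATCAGGAGATGCGAGTCCACAGAAACCCGCACTCACGAGAGCACATCCATTCCGGTTACCCACCGGTCCATGACCGCCATAGAATTACAGCCGCTGAGGTCGTATCG
pabs_codons:
- 9
- 11
- 13
- 26
- 28
- 30
- 32
- 37
- 38
- 47
- 56
- 57
- 60
- 61
- 65
- 67
- 68
- 70
- 71
- 72
- 74
- 76
- 78
- 81
primers:
  forward: TATCGGTCTACATTAGAC
  reverse: CTCTCGTGAGTGCGGGTT
  forward_start: 61
  reverse_start: 184
max_artifact_count: 2
max_nt_diff: 2
min_individuals: 2
min_clones: 1
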