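# E. coli CheY reference for anchoring receiver-domain alignments.
# Key/value TSV; sequence is ungapped, numbering starts at Met1 (UniProt P0AE67).
# Landmarks: DD1/DD2 = acidic metal-binding pair (Asp12/Asp13), D = Asp57
# phosphorylation site, T = Thr87, K = Lys109.
reference_id	CheY_Ecoli_P0AE67
sequence	MADKELKFLVVDDFSTMRRIVRNLLKELGFNNVEEAEDGVDALNKLQAGGYGFVISDWNMPNMDGLELLKTIRADGAMSALPVLMVTAEAKKENIIAAAQAGASGYVVKPFTAATLEEKLNKIFEKLGM
DD1	12
DD2	13
D	57
T	87
K	109
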