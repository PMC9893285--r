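# Hallmark ungapped motifs of celiac-disease-associated peptides.
# Columns: pattern <tab> occurrences in catalogued CD-associated peptides
#          <tab> occurrences in non-associated peptides.
# Ordered by coverage among known positives (first-match attribution order).
QPF	276	0
PQQP	41	0
PYP	33	0
QPQQ	28	0
PFP	14	0
PEQ	12	0
FPQP	4	0
FPQQ	2	0
PQLP	1	0
QQPF	170	0
QPQ	350	1
PQPQ	189	1
QQPQ	131	1
PQL	84	1
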