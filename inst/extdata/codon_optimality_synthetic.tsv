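codon	class
TTT	non-optimal
TTC	optimal
TTA	non-optimal
TTG	optimal
CTT	non-optimal
CTC	non-optimal
CTA	non-optimal
CTG	non-optimal
ATT	optimal
ATC	optimal
ATA	non-optimal
ATG	optimal
GTT	optimal
GTC	optimal
GTA	non-optimal
GTG	non-optimal
TCT	optimal
TCC	optimal
TCA	non-optimal
TCG	non-optimal
AGT	non-optimal
AGC	non-optimal
CCT	non-optimal
CCC	non-optimal
CCA	optimal
CCG	non-optimal
ACT	optimal
ACC	optimal
ACA	non-optimal
ACG	non-optimal
GCT	optimal
GCC	optimal
GCA	non-optimal
GCG	non-optimal
TAT	non-optimal
TAC	optimal
CAT	non-optimal
CAC	optimal
CAA	optimal
CAG	non-optimal
AAT	non-optimal
AAC	optimal
AAA	non-optimal
AAG	optimal
GAT	non-optimal
GAC	optimal
GAA	optimal
GAG	non-optimal
TGT	optimal
TGC	non-optimal
TGG	optimal
CGT	non-optimal
CGC	non-optimal
CGA	non-optimal
CGG	non-optimal
AGA	optimal
AGG	non-optimal
GGT	optimal
GGC	non-optimal
GGA	non-optimal
GGG	non-optimal
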