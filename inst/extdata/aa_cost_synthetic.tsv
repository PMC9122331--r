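# Per-residue biosynthetic cost table (SYNTHETIC PLACEHOLDER VALUES).
#
# energy_cost: ATP equivalents consumed per residue synthesized. These are
#   the widely used Akashi & Gojobori (2002, PNAS 99:3695) ATP costs, shipped
#   as a documented default because the human-specific energy-cost-per-amino-
#   acid values this analysis was designed around are not redistributable
#   here. Replace this file to use another cost model; it is the single
#   source of truth for avECPA.
# decay_normalized_metric: energy cost normalized by amino-acid decay rate.
#   PLACEHOLDER values constructed so that the qualitative classification is
#   reproduced (cysteine, aspartate, asparagine metabolically expensive at
#   metric > 60; small cheap residues affordable at metric < 20). Do not
#   interpret the numbers quantitatively.
aa	energy_cost	decay_normalized_metric
A	11.7	12
R	27.3	35
N	14.7	66
D	12.7	72
C	24.7	88
Q	16.3	30
E	15.3	28
G	11.7	10
H	38.3	45
I	32.3	38
L	27.3	26
K	30.3	33
M	34.3	55
F	52.0	48
P	20.3	18
S	11.7	14
T	21.5	22
W	74.3	58
Y	50.0	42
V	23.3	24
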