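# longest-prefix ancestry classification of haplogroup labels
prefix	class
M	South Asian
M1	North African
U6	North African
U	West Eurasian
K	West Eurasian
H	West Eurasian
V	West Eurasian
HV	West Eurasian
R0	West Eurasian
JT	West Eurasian
J	West Eurasian
T	West Eurasian
N1	West Eurasian
N2	West Eurasian
W	West Eurasian
X	West Eurasian
I	West Eurasian
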