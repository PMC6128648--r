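aa	total_area
A	113.303
R	238.616
N	155.992
D	154.882
C	139.018
Q	187.376
E	185.089
G	86.383
H	183.901
I	176.727
L	164.501
K	203.466
M	193.405
F	203.749
P	138.737
S	125.328
T	149.427
W	248.849
Y	222.552
V	155.594
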