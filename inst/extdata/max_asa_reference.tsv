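# Reference maximal ASA (A^2), theoretical Gly-X-Gly whole-residue maxima.
# sidechain = total - Gly total (104.0); Gly keeps its whole-residue value.
aa	total	sidechain
A	129.0	25.0
R	274.0	170.0
N	195.0	91.0
D	193.0	89.0
C	167.0	63.0
E	223.0	119.0
Q	225.0	121.0
G	104.0	104.0
H	224.0	120.0
I	197.0	93.0
L	201.0	97.0
K	236.0	132.0
M	224.0	120.0
F	240.0	136.0
P	159.0	55.0
S	155.0	51.0
T	172.0	68.0
W	285.0	181.0
Y	263.0	159.0
V	174.0	70.0
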