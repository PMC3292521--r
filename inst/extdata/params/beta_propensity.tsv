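# Beta-sheet propensity scale (raw, dimensionless; larger = stronger
# sheet former; beta-branched and aromatic residues rank highest).
# At load time the scale is affinely rescaled onto the numeric range of
# the inverted helix force-constant scale so the two propensity terms
# act on comparable magnitudes.
aa	raw
T	1.10
I	1.00
Y	0.96
F	0.86
V	0.82
W	0.54
M	0.46
L	0.51
C	0.52
R	0.45
Q	0.37
S	0.70
K	0.27
H	0.30
A	0.00
E	0.01
N	0.08
G	-1.20
D	-0.94
P	-1.80
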