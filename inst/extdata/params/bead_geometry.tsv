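# Two-bead geometry, derived once from idealized side-chain templates:
#   b      Calpha -> Cbeta-centroid bond length, Angstrom (NA for Gly)
#   r      Cbeta bead radius = side-chain radius of gyration about the
#          centroid, Angstrom (proportionality constant 1.0; NA for Gly)
#   theta0 equilibrium Calpha(i-1)-Calpha(i)-Cbeta(i) bend angle, rad
aa	b	r	theta0
A	1.53	0.85	2.10
C	2.00	1.30	2.10
D	2.50	1.40	2.10
E	3.10	1.60	2.10
F	3.40	1.90	2.10
G	NA	NA	2.10
H	3.10	1.70	2.10
I	2.30	1.45	2.05
K	3.50	1.80	2.10
L	2.60	1.50	2.10
M	2.70	1.60	2.10
N	2.50	1.45	2.10
P	1.90	1.25	2.00
Q	3.10	1.65	2.10
R	4.10	2.00	2.10
S	1.90	1.10	2.10
T	1.90	1.20	2.05
V	2.00	1.30	2.05
W	3.90	2.10	2.10
Y	3.80	2.00	2.10
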