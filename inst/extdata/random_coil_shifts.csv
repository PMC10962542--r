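# Random-coil Calpha/Halpha reference shifts (ppm), approximate transcription
# of widely used disordered-peptide coil compilations (DSS-referenced, near-
# neutral pH, 25 C). Convenience default only: supply the coil table matched
# to your conditions for publication work. The pS row reuses the Ser values.
residue,delta_Ca_ppm,delta_Ha_ppm
A,52.5,4.32
C,58.2,4.55
D,54.2,4.64
E,56.6,4.35
F,57.7,4.62
G,45.1,3.96
H,55.0,4.73
I,61.1,4.17
K,56.2,4.32
L,55.1,4.34
M,55.4,4.48
N,53.1,4.74
P,63.3,4.42
Q,55.7,4.34
R,56.0,4.34
S,58.3,4.47
T,61.8,4.35
V,62.2,4.12
W,57.5,4.66
Y,57.9,4.55
pS,58.3,4.47
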