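# Zero wedge set: all roll/tilt 0, twist 36.0 deg, rise 3.38 A.
# Produces a straight helical axis; intended for testing and as the
# null reference for curvature profiles.
dinucleotide,roll,tilt,twist,rise
AA,0.0,0.0,36.0,3.38
AC,0.0,0.0,36.0,3.38
AG,0.0,0.0,36.0,3.38
AT,0.0,0.0,36.0,3.38
CA,0.0,0.0,36.0,3.38
CC,0.0,0.0,36.0,3.38
CG,0.0,0.0,36.0,3.38
CT,0.0,0.0,36.0,3.38
GA,0.0,0.0,36.0,3.38
GC,0.0,0.0,36.0,3.38
GG,0.0,0.0,36.0,3.38
GT,0.0,0.0,36.0,3.38
TA,0.0,0.0,36.0,3.38
TC,0.0,0.0,36.0,3.38
TG,0.0,0.0,36.0,3.38
TT,0.0,0.0,36.0,3.38
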