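# A-tract wedge parameter set: AA/TT steps carry an 8.7 degree wedge
# decomposed into roll 8.4 / tilt 2.4 degrees (Ulanovsky & Trifonov,
# Nature 326:720-722 (1987); wedge-model estimate for ApA). All other
# steps are straight. Twist 36.0 deg/step (10 bp helical repeat),
# rise 3.38 A/step. Reverse-complement convention: roll(rc) = roll,
# tilt(rc) = -tilt, twist(rc) = twist.
dinucleotide,roll,tilt,twist,rise
AA,8.4,2.4,36.0,3.38
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
TT,8.4,-2.4,36.0,3.38
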