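# SYNTHETIC chamber calibration for examples and tests only -- NOT clinical data.
# Illustrative plane-parallel chamber with plausible kQ magnitudes; real
# beam-quality factors must come from the user's calibration certificate
# and protocol tables.
# columns: Rres_mm kQ
name: markus-synthetic
N_DwQ0: 1.472
2 1.004
5 1.002
10 1.001
15 1.000
20 0.999
25 0.998
30 0.997
35 0.996
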