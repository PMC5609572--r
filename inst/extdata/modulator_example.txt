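# example modulator step file: thickness_mm weight (zero thickness = air gap)
mode: relative
0 0.35
0.8 0.20
1.6 0.15
2.4 0.12
3.2 0.10
4.0 0.08
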