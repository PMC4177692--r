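pop	n	lon	lat
A	10	26.49027	40.27444
B	11	26.43000	40.12527
C	10	27.39277	39.80000
C2	10	27.41027	39.79111
D	10	28.64250	39.61416
E	10	29.63361	39.53944
F	10	31.20166	39.53888
G	10	32.45583	39.50111
H	10	34.84166	38.74055
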