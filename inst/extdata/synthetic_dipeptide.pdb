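MODEL        1
ATOM      1 X1   TPA A   1       0.000   0.000   0.000  1.00  0.00
ATOM      2 X2   TPA A   1       0.000   4.000   0.000  1.00  0.00
ATOM      3 X1   TPB B   1       5.000   0.000   0.000  1.00  0.00
ENDMDL
MODEL        2
ATOM      1 X1   TPA A   1       0.000   0.000   0.000  1.00  0.00
ATOM      2 X2   TPA A   1       0.000   4.000   0.000  1.00  0.00
ATOM      3 X1   TPB B   1       8.000   0.000   0.000  1.00  0.00
ENDMDL
END
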