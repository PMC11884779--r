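H KYTJ820101
D Hydropathy index (Kyte-Doolittle, 1982)
A Kyte, J. and Doolittle, R.F.
T A simple method for displaying the hydropathic character of a protein
J J. Mol. Biol. 157, 105-132 (1982)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
     3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H SYNTH000001
D Synthetic linear ramp (test fixture, not a real AAindex record)
A none
T synthetic
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     1.0     2.0     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0
    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0
//
H SYNTH000002
D Synthetic record with missing values (test fixture)
A none
T synthetic
J none
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.5      NA     1.5     2.5     3.5     4.5     5.5     6.5     7.5     8.5
     9.5    10.5    11.5    12.5    13.5    14.5    15.5    16.5    17.5    18.5
//
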