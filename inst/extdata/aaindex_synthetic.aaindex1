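H SYNH000001
D Synthetic hydropathy-like scale (test fixture, invented values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
   1.8    -4.5    -3.5    -3.5     2.5    -3.5    -3.5    -0.4    -3.2     4.5
   3.8    -3.9     1.9     2.8    -1.6    -0.8    -0.7    -0.9    -1.3     4.2
//
H SYNV000002
D Synthetic residue-volume-like scale (test fixture, invented values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  88.6   173.4   114.1   111.1   108.5   143.8   138.4    60.1   153.2   166.7
 166.7   168.6   162.9   189.9   112.7    89.0   116.1   227.8   193.6   140.0
//
H SYNA000003
D Synthetic helix-propensity-like scale (test fixture, invented values)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  1.42    0.98    0.67    1.01    0.70    1.11    1.51    0.57    1.00    1.08
  1.21    1.16    1.45    1.13    0.57    0.77    0.83    1.08    0.69    1.06
//
H SYNX000004
D Synthetic incomplete scale (test fixture; must be excluded by parsers)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
  0.10    0.20      NA    0.40    0.50    0.60    0.70    0.80    0.90    1.00
  1.10    1.20    1.30      NA    1.50    1.60    1.70    1.80    1.90    2.00
//
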