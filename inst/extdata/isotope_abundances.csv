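element,isotope,mass,abundance
H,1,1.0078250319,0.999885
H,2,2.0141017779,0.000115
C,12,12.0,0.9893
C,13,13.0033548351,0.0107
N,14,14.0030740052,0.99636
N,15,15.0001088984,0.00364
O,16,15.9949146221,0.99757
O,17,16.9991315,0.00038
O,18,17.9991604,0.00205
S,32,31.97207069,0.9499
S,33,32.9714585,0.0075
S,34,33.96786683,0.0425
S,36,35.96708088,0.0001
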