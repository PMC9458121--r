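VDW HP 1.1000 0.0157
HrmStr1 CT HC 340.00 1.0900
HrmBnd1 C N H 50.00 120.0001
AmbTrs NJ CJ ND CK 0 180 0 0 0.000 4.750 0.000 0.000 1.0
ImpTrs CJ NJ CD NH 1.1 180.0 2.0
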