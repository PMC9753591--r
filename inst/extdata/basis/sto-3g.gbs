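! STO-3G minimal basis, Gaussian94 format (H, O)
****
H     0
S   3   1.00
      3.42525091         0.15432897
      0.62391373         0.53532814
      0.16885540         0.44463454
****
O     0
S   3   1.00
    130.7093200          0.15432897
     23.8088610          0.53532814
      6.4436083          0.44463454
SP   3   1.00
      5.0331513         -0.09996723         0.15591627
      1.1695961          0.39951283         0.60768372
      0.3803890          0.70011547         0.39195739
****
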