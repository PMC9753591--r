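! 6-31G split-valence basis, Gaussian94 format (H, O)
****
H     0
S   3   1.00
     18.7311370          0.03349460
      2.8253937          0.23472695
      0.6401217          0.81375733
S   1   1.00
      0.1612778          1.00000000
****
O     0
S   6   1.00
   5484.6717000          0.00183110
    825.2349500          0.01395010
    188.0469600          0.06844510
     52.9645000          0.23271430
     16.8975700          0.47019300
      5.7996353          0.35852090
SP   3   1.00
     15.5396160         -0.11077750          0.07087430
      3.5999336         -0.14802630          0.33975280
      1.0137618          1.13076700          0.72715860
SP   1   1.00
      0.2700058          1.00000000          1.00000000
****
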