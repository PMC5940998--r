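$RXN
ethyl acetate hydrolysis
  rxnid

  2  2
$MOL
ethyl acetate
  rxnid

  6  5  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8700    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7400    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.6100    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.4800    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.3500    0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
  3  4  1  0  0  0  0
  4  5  1  0  0  0  0
  4  6  2  0  0  0  0
M  END
$MOL
water
  rxnid

  1  0  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
M  END
$MOL
acetic acid
  rxnid

  4  3  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8700    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7400    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.6100    0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  2  0  0  0  0
  2  4  1  0  0  0  0
M  END
$MOL
ethanol
  rxnid

  3  2  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8700    0.5000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.7400    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  2  3  1  0  0  0  0
M  END
$RXNID-AGENTS
$MOL
sulfuric acid
  rxnid

  5  4  0  0  0  0  0  0  0  0999 V2000
    0.0000    0.0000    0.0000 S   0  0  0  0  0  0  0  0  0  0  0  0
    0.8700    0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.7400    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.6100    0.5000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    3.4800    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  2  0  0  0  0
  1  3  2  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
M  END
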