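# TG-43U1 parameter set: Cs-137 Selectron pellet, first slot inside the
# cylindrical vaginal applicator (water phantom).
# lambda and sk are placeholders (1.0): dose rates from this file are in
# units of Sk*Lambda; edit them for absolute calibration.
[meta]
lambda = 1.0
sk = 1.0
position_index = 1
label = Cs-137 Selectron pellet, slot 1, cylindrical applicator

[g]
# r_cm  g
1   1.000
2   0.998
3   0.985
4   0.971
5   0.947
6   0.934
7   0.917
8   0.906
9   0.902
10  0.865

[F]
# first row: angles (deg); rows: r_cm followed by F values
15 30 45 60 75 90 105 120 135 150 165
3  0.903 0.956 1.000 0.999 1.003 1.000 1.010 1.003 0.948 0.944 0.902
5  0.921 0.961 0.996 0.992 1.005 1.000 1.007 1.006 0.988 0.953 0.939
7  0.920 0.979 0.997 0.995 1.002 1.000 1.010 1.003 0.993 0.958 0.938
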