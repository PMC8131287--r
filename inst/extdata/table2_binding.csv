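guest,fm_mp2,fm_mp2_err,c36_s6,c36_s6_err,fm_pm6,fm_pm6_err,experimental,experimental_err
G1,-12.75,0.67,-10.25,0.69,-9.90,0.90,-7.05,0.04
G2,-3.82,0.75,-8.38,0.75,-8.38,0.65,-9.93,0.03
G3,-15.33,0.87,-15.95,0.63,-11.75,0.88,-11.63,0.03
G4,-17.62,0.98,-14.96,1.00,-11.93,0.64,-11.22,0.04
G5N,-4.10,1.05,-11.32,1.03,-10.41,1.05,NA,NA
G5P,-13.26,0.76,-8.73,0.78,-11.70,1.06,NA,NA
G5*,-12.91,0.91,-10.90,0.91,-11.40,1.05,-12.32,0.04
G6,-16.93,0.66,-12.56,0.63,-14.23,0.61,-14.07,0.06
G7,-12.44,0.92,-8.25,1.03,-10.08,0.84,-7.92,0.04
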