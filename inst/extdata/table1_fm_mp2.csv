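guest,rest_off,rest_off_err,rest_on,rest_on_err,reus,reus_err,bind,bind_err,avg_bind,avg_bind_err
G1,-0.74,0.11,0.30,0.08,-12.30,0.47,-12.75,0.67,NA,NA
G2,-0.42,0.31,0.13,0.01,-3.53,0.44,-3.82,0.75,NA,NA
G3,-0.64,0.11,0.17,0.01,-14.86,0.76,-15.33,0.87,NA,NA
G4,-0.70,0.34,0.16,0.02,-17.07,0.62,-17.62,0.98,NA,NA
G5NR,-0.68,0.11,0.48,0.29,-4.02,0.47,-4.21,0.87,-4.10,1.05
G5NS,-0.67,0.11,0.68,0.43,-3.99,0.69,-3.98,1.23,-4.10,1.05
G5PR,-0.69,0.11,0.39,0.14,-13.00,0.49,-13.30,0.74,-13.26,0.76
G5PS,-0.69,0.11,0.18,0.06,-12.72,0.59,-13.22,0.77,-13.26,0.76
G6,-0.69,0.11,0.18,0.01,-16.42,0.54,-16.93,0.66,NA,NA
G7,-0.62,0.11,0.23,0.18,-12.06,0.64,-12.44,0.92,NA,NA
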