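center,log_sir,sd,q2.5,q97.5,sir,sir_lower,sir_upper
AI,-0.23,0.17,-0.55,0.10,0.80,0.58,1.11
AN,-0.16,0.09,-0.32,0.01,0.85,0.72,1.01
BI,-0.99,0.16,-1.30,-0.67,0.37,0.27,0.51
BN,-0.24,0.08,-0.40,-0.07,0.79,0.67,0.93
CI,-0.36,0.16,-0.67,-0.04,0.70,0.51,0.96
CN,-0.14,0.08,-0.29,0.01,0.87,0.75,1.01
DI,0.84,0.16,0.53,1.16,2.31,1.70,3.18
DN,0.49,0.08,0.34,0.63,1.63,1.41,1.89
EI,-0.50,0.16,-0.82,-0.18,0.61,0.44,0.84
EN,-0.36,0.08,-0.51,-0.21,0.70,0.60,0.81
FI,-14.21,0.17,-14.54,-13.88,0.00,0.00,0.00
FN,-0.26,0.08,-0.42,-0.11,0.77,0.66,0.89
GI,-0.99,0.16,-1.30,-0.67,0.37,0.27,0.51
GN,-0.07,0.08,-0.22,0.08,0.93,0.80,1.09
HI,0.49,0.17,0.16,0.82,1.63,1.17,2.27
HN,0.07,0.09,-0.10,0.24,1.07,0.91,1.28
II,-14.40,0.16,-14.71,-14.08,0.00,0.00,0.00
IN,-0.01,0.08,-0.16,0.14,0.99,0.85,1.15
JI,0.61,0.16,0.30,0.94,1.85,1.35,2.56
JN,0.46,0.08,0.31,0.61,1.59,1.37,1.85
OI,-0.11,0.16,-0.42,0.20,0.89,0.66,1.22
ON,0.05,0.08,-0.10,0.19,1.05,0.90,1.21
PI,-13.50,0.17,-13.82,-13.17,0.00,0.00,0.00
PN,-0.07,0.08,-0.23,0.08,0.93,0.79,1.09
QI,-0.67,0.18,-1.03,-0.30,0.51,0.36,0.74
QN,-0.02,0.14,-0.28,0.25,0.98,0.75,1.28
RI,-0.27,0.16,-0.58,0.06,0.77,0.56,1.06
RN,-0.18,0.08,-0.33,-0.01,0.84,0.72,0.99
SI,1.00,0.17,0.68,1.33,2.72,1.98,3.77
SN,-0.07,0.08,-0.21,0.08,0.94,0.81,1.09
TI,1.00,0.17,0.67,1.34,2.72,1.96,3.82
TN,0.61,0.09,0.44,0.77,1.84,1.55,2.17
UI,0.49,0.17,0.17,0.81,1.63,1.18,2.25
UN,0.08,0.07,-0.06,0.22,1.08,0.94,1.25
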