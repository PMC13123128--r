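parameter,mean,sd,q2.5,q97.5,or,or_lower,or_upper
Intercept,-2.38,0.49,-3.49,-1.48,0.09,0.03,0.23
Male,0.14,0.05,0.03,0.24,1.15,1.03,1.28
Age 26-35,-0.14,0.13,-0.41,0.11,0.87,0.67,1.12
Age 36-45,-0.31,0.12,-0.55,-0.07,0.73,0.57,0.93
Age 46-55,-0.82,0.12,-1.06,-0.58,0.44,0.35,0.56
Age 56-65,-1.14,0.12,-1.38,-0.91,0.32,0.25,0.40
Age 66-75,-2.35,0.13,-2.61,-2.09,0.10,0.07,0.12
Age 76+,-5.25,0.36,-6.02,-4.59,0.01,0.00,0.01
Non_Indigenous,1.73,0.24,1.27,2.20,5.63,3.57,9.00
Lung disease,-0.81,0.12,-1.05,-0.57,0.45,0.35,0.56
Diabetes,-1.08,0.06,-1.20,-0.95,0.34,0.30,0.39
CVD,1.04,0.39,0.37,1.99,2.84,1.44,7.33
Late referral,-0.93,0.08,-1.09,-0.76,0.40,0.33,0.47
Obesity,-0.52,0.06,-0.64,-0.40,0.59,0.53,0.67
MMM 2,0.20,0.10,0.00,0.40,1.22,1.00,1.49
MMM 3,-0.02,0.13,-0.27,0.24,0.98,0.76,1.27
MMM 4,-0.02,0.16,-0.33,0.28,0.98,0.72,1.32
MMM 5,0.08,0.09,-0.09,0.25,1.08,0.91,1.28
MMM 6,-0.31,0.16,-0.63,0.00,0.73,0.53,1.00
MMM 7,0.11,0.17,-0.22,0.43,1.12,0.80,1.54
Period 2010-2014,-0.23,0.07,-0.38,-0.09,0.79,0.69,0.92
Period 2015-2018,-0.29,0.08,-0.44,-0.14,0.75,0.64,0.87
Period 2019-2023,-1.27,0.08,-1.44,-1.11,0.28,0.24,0.33
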