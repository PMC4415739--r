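frequency_khz,0.1,0.2,0.3,0.4,0.5,0.6,0.7,0.8,0.9,1.0
5,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.50e+03,9.20e+03,1.40e+04,2.85e+04,4.70e+04
10,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.50e+03,9.20e+03,1.40e+04,2.62e+04,3.90e+04
20,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.50e+03,9.20e+03,1.40e+04,2.10e+04,2.80e+04
30,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.50e+03,9.20e+03,1.40e+04,1.75e+04,2.10e+04
40,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.40e+03,9.20e+03,1.35e+04,1.50e+04,1.70e+04
50,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.30e+03,8.80e+03,1.30e+04,1.33e+04,1.40e+04
60,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.20e+03,8.60e+03,1.25e+04,1.23e+04,1.20e+04
70,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.10e+03,8.43e+03,1.20e+04,1.15e+04,1.10e+04
80,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,7.00e+03,8.26e+03,1.15e+04,1.05e+04,1.00e+04
90,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,6.85e+03,8.09e+03,1.11e+04,9.70e+03,9.00e+03
100,5.00e+03,5.20e+03,5.50e+03,5.90e+03,6.30e+03,6.70e+03,7.92e+03,1.07e+04,9.20e+03,8.50e+03
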