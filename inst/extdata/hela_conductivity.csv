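frequency_khz,0.1,0.2,0.3,0.4,0.5,0.6,0.7,0.8,0.9,1.0
5,2.25e-04,2.60e-04,2.95e-04,3.60e-04,4.25e-04,5.90e-04,8.85e-04,1.70e-03,4.80e-03,7.64e-03
10,4.25e-04,4.80e-04,5.55e-04,6.60e-04,7.75e-04,1.09e-03,1.64e-03,3.30e-03,9.95e-03,1.53e-02
20,7.30e-04,8.20e-04,9.55e-04,1.10e-03,1.32e-03,1.90e-03,2.88e-03,6.10e-03,1.85e-02,2.80e-02
30,1.10e-03,1.20e-03,1.40e-03,1.60e-03,1.92e-03,2.75e-03,4.18e-03,8.80e-03,2.43e-02,3.60e-02
40,1.60e-03,1.70e-03,2.00e-03,2.30e-03,2.65e-03,3.70e-03,5.50e-03,1.14e-02,2.83e-02,4.10e-02
50,2.30e-03,2.40e-03,2.80e-03,3.20e-03,3.55e-03,4.80e-03,7.00e-03,1.41e-02,3.18e-02,4.35e-02
60,3.20e-03,3.30e-03,3.80e-03,4.20e-03,4.70e-03,6.30e-03,8.73e-03,1.71e-02,3.60e-02,4.55e-02
70,4.20e-03,4.30e-03,4.90e-03,5.40e-03,6.00e-03,7.80e-03,1.06E-02,1.98e-02,3.90e-02,4.93e-02
80,5.40e-03,5.50e-03,6.20e-03,6.90e-03,7.50e-03,9.50e-03,1.27e-02,2.28e-02,4.10e-02,5.13e-02
90,6.70e-03,6.80e-03,7.70e-03,8.40e-03,9.10e-03,1.11e-02,1.49e-02,2.56e-02,4.30e-02,5.20e-02
100,8.20e-03,8.30e-03,9.30e-03,1.01e-02,1.09e-02,1.31e-02,1.72e-02,2.86e-02,4.59e-02,5.49e-02
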