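# zonal wall-shear preset: high-WSS region proximal to the TAWSS peak
# (acceleration zone), giving a positive region gradient direction
tau_impingement: 20.0
tau_peak: 95.0
peak_distance: 7.0
decay_length: 3.0
pulsatility: 0.4
reversal_fraction: 0.1
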