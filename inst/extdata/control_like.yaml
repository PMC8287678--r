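# zonal wall-shear preset: shallow impingement dip with an early peak, so
# the high-WSS region falls in the recovery zone (negative gradient
# direction)
tau_impingement: 95.0
tau_peak: 110.0
peak_distance: 1.5
decay_length: 2.8
pulsatility: 0.4
reversal_fraction: 0.12
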