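# Synthetic calibration of the time-dependent clock correction.
# Model: expected substitutions rho(t) = mu*L*((1-f)*t + f*tau*(1-exp(-t/tau)))
# f    = fraction of new mutations transiently tolerated but eventually
#        purged by purifying selection; chosen so the long-term rate
#        (1-f)*mu equals 1.665e-8 subs/site/yr when mu = 2.355e-8
# tau  = purging timescale in years
param	value
f	0.29299
tau_years	12000
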