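upper_respiratory_infection	respiratory_disease
lower_respiratory_infection	respiratory_disease
pharyngitis	upper_respiratory_infection
tonsillitis	upper_respiratory_infection
pneumonia	lower_respiratory_infection
interstitial_pneumonia	pneumonia
lobar_pneumonia	pneumonia
bronchitis	lower_respiratory_infection
asthma	respiratory_disease
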