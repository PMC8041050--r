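respiratory_disease	disorder of respiratory system	respiratory disease
upper_respiratory_infection	upper respiratory tract infection	URTI
lower_respiratory_infection	lower respiratory tract infection	
pharyngitis	pharyngitis	sore throat inflammation|inflammation of the pharynx
tonsillitis	tonsillitis	inflammation of the tonsils
pneumonia	pneumonia	lung infection|lung inflammation
interstitial_pneumonia	interstitial pneumonia	interstitial lung infection
lobar_pneumonia	lobar pneumonia	
bronchitis	bronchitis	bronchial inflammation
asthma	asthma	bronchial asthma
gastroenteritis	gastroenteritis	stomach flu
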