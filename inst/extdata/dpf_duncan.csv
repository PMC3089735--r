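# Age-dependent differential pathlength factor coefficients, DPF(age) = a + b * age^c.
# Source: Duncan A, Meek JH, Clemence M, et al. (1996) "Measurement of cranial
# optical path length as a function of age using phase resolved near infrared
# spectroscopy", Pediatr Res / Phys Med Biol tabulation; rows flagged 'derived'
# were obtained by linear interpolation (764 nm) or extrapolation (859 nm) of
# the published (a, b, c) across wavelength for the Oxymon centre wavelengths.
# This file is user-replaceable; dpf() requires an exact wavelength row.
wavelength_nm,a,b,c,provenance
690,5.38,0.049,0.877,published
744,5.11,0.106,0.723,published
764,5.071905,0.093619,0.751889,derived
807,4.99,0.067,0.814,published
832,4.67,0.062,0.819,published
859,4.3244,0.0566,0.8244,derived
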