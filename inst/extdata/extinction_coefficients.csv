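# Specific (molar, decadic) extinction coefficients of oxy- and
# deoxyhaemoglobin in cm^-1 M^-1. Approximate values compiled from the
# Gratzer & Kollias haemoglobin data as tabulated by S. Prahl (Oregon Medical
# Laser Center, https://omlc.org/spectra/hemoglobin/), rounded; linear
# interpolation to the requested wavelength is applied at load time.
# This table is user-replaceable: the conversion's correctness is defined by
# its algebra (exact round-trip, nonsingular 2x2 unmixing), not by any one
# published compilation, which differ by a few percent.
wavelength_nm,eps_o2hb_cm1_M1,eps_hhb_cm1_M1
690,276.0,2052.0
700,290.0,1794.3
720,390.0,1244.8
740,446.0,1115.9
750,518.0,1405.2
760,586.0,1548.5
770,650.0,1311.9
780,710.0,1075.4
800,816.0,761.7
820,916.0,717.1
840,1022.0,692.4
860,1092.0,700.0
880,1154.0,726.4
900,1198.0,754.2
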