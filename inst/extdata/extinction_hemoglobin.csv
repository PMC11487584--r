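# Molar (decadic) extinction coefficients of human hemoglobin.
# Units: 1/(cm * mol/L). Values interpolated from a standard literature
# compilation of oxy- and deoxyhemoglobin spectra; version 2024-01.
# mu_a(lambda) = ln(10) * [eps_hbo2 * C_HbO2 + eps_hhb * C_HHb]
wavelength_nm,eps_hbo2,eps_hhb
687,288,2075
785,735,880
830,974,693
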