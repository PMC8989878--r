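# Hemoglobin extinction coefficients at the four instrument wavelengths,
# interpolated from the standard compiled whole-blood oxy/deoxy-hemoglobin
# molar extinction spectrum (Gratzer/Kollias compilation as distributed by
# the OMLC tabulation). Conversion applied here:
#   eps [mm^-1 uM^-1] = ln(10) * eps_molar [cm^-1 M^-1] * 1e-6 [M/uM] / 10 [mm/cm]
#                     = 2.302585e-7 * eps_molar
# Source molar values (cm^-1 M^-1): 659 nm HbO2 320, HHb 3230; 691 nm HbO2 285,
# HHb 2000; 731 nm HbO2 390, HHb 1080; 851 nm HbO2 1058, HHb 691.
wavelength_nm,eps_HbO2_per_mm_per_uM,eps_HHb_per_mm_per_uM
659,7.3683e-05,7.4374e-04
691,6.5624e-05,4.6052e-04
731,8.9801e-05,2.4868e-04
851,2.4361e-04,1.5911e-04
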