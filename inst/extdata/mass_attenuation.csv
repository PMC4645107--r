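# Mass attenuation (mu/rho) and mass energy-absorption (mu_en/rho)
# coefficients, cm^2/g, on a small photon-energy grid bracketing 8.48 keV.
# Representative values interpolated (log-log) from standard references.
# density_g_cm3 is the bulk density used to convert mu/rho to linear mu.
medium,energy_keV,mu_over_rho_cm2_g,mu_en_over_rho_cm2_g,density_g_cm3
Si,8.0,61.7,60.0,2.33
Si,8.48,52.0,50.5,2.33
Si,10.0,32.3,31.2,2.33
water,8.0,10.37,9.16,1.0
water,8.48,8.71,7.70,1.0
water,10.0,5.33,4.94,1.0
protein,8.0,6.0,5.9,1.35
protein,8.48,5.1,5.0,1.35
protein,10.0,3.2,3.1,1.35
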