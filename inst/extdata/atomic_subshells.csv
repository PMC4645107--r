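# Subshell occupancies and binding energies (keV) for the shipped elements,
# plus one "(total)" row per element carrying the total photoabsorption cross
# section (barn) at the reference photon energy and the charge floor q_floor
# (charge state at which photoionization ceases because the remaining binding
# energy exceeds the reference photon energy).
# Values are representative numbers interpolated from standard X-ray data
# references; binding energies to the precision shown.
element,Z,subshell,occupancy,binding_energy_keV,sigma_total_barn,reference_energy_keV,q_floor
C,6,1s,2,0.2842,,,
C,6,2s,2,0.0194,,,
C,6,2p,2,0.0106,,,
C,6,(total),,,722,8.48,6
Gd,64,K,2,50.239,,,
Gd,64,LI,2,8.376,,,
Gd,64,LII,2,7.930,,,
Gd,64,LIII,4,7.243,,,
Gd,64,MI,2,1.881,,,
Gd,64,MII,2,1.688,,,
Gd,64,MIII,4,1.544,,,
Gd,64,MIV,4,1.218,,,
Gd,64,MV,6,1.185,,,
Gd,64,NI,2,0.3758,,,
Gd,64,NII,2,0.2885,,,
Gd,64,NIII,4,0.2709,,,
Gd,64,NIV,4,0.1432,,,
Gd,64,NV,6,0.1408,,,
Gd,64,NVI,7,0.0086,,,
Gd,64,OI,2,0.0361,,,
Gd,64,OII,2,0.0203,,,
Gd,64,OIII,4,0.0203,,,
Gd,64,OIV,1,0.0060,,,
Gd,64,PI,2,0.0060,,,
Gd,64,(total),,,1.04e5,8.48,33
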