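label,length_um,width_um,moment
needle,0.9,0.08,1.481e-15
needle,1.1,0.09,1.975e-15
needle,1.3,0.09,2.304e-15
needle,1.4,0.10,2.551e-15
needle,1.6,0.10,2.880e-15
needle,2.0,0.10,7.406e-15
giant bullet,1.2,0.35,2.057e-15
giant bullet,1.3,0.38,2.386e-15
giant bullet,1.4,0.40,2.633e-15
giant bullet,1.5,0.42,2.962e-15
giant bullet,1.7,0.45,3.374e-15
giant bullet,1.9,0.50,3.868e-15
kinked giant bullet,1.8,0.45,4.279e-15
kinked giant bullet,2.0,0.50,4.773e-15
kinked giant bullet,2.2,0.55,5.431e-15
spearhead,2.0,1.00,6.994e-15
spearhead,2.1,1.05,7.817e-15
spearhead,2.2,1.05,8.229e-15
spearhead,2.25,1.10,8.640e-15
spearhead,2.3,1.10,9.216e-15
spearhead,2.4,1.15,9.957e-15
spindle,2.8,0.90,2.551e-14
spindle,3.1,1.00,3.415e-14
spindle,3.4,1.10,4.197e-14
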