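# Synthetic glomerular sieving table: sieving coefficient theta versus
# solute Stokes radius a_e (nm).  These values EMULATE the shape of
# published Ficoll/protein glomerular sieving measurements (steep
# size-selectivity cutoff near 3 nm, theta < 1e-3 above 4 nm); they are a
# synthetic stand-in generated for this package, not digitized data.
a_e_nm,theta
1.4,0.999
1.8,0.993
2.2,0.940
2.4,0.845
2.6,0.630
2.8,0.368
3.0,0.160
3.2,0.057
3.4,0.021
3.6,0.0065
3.9,0.0013
4.2,0.00024
4.5,0.000045
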