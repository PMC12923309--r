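layer,wavelength_nm,mua,mus,unit,g,n,thickness_mm
epidermis,808,0.025,18.0,per_mm,0.9,1.37,0.1
epidermis,852,0.023,17.0,per_mm,0.9,1.37,0.1
epidermis,890,0.022,16.0,per_mm,0.9,1.37,0.1
dermis,808,0.012,12.0,per_mm,0.9,1.37,2.0
dermis,852,0.013,11.0,per_mm,0.9,1.37,2.0
dermis,890,0.014,10.5,per_mm,0.9,1.37,2.0
fat,808,0.010,10.0,per_mm,0.9,1.37,6.0
fat,852,0.011,9.5,per_mm,0.9,1.37,6.0
fat,890,0.012,9.0,per_mm,0.9,1.37,6.0
tumor,808,0.015,8.0,per_mm,0.9,1.37,2.0
tumor,852,0.016,7.5,per_mm,0.9,1.37,2.0
tumor,890,0.017,7.0,per_mm,0.9,1.37,2.0
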