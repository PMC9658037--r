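factor,trait,sense,goal,gain_percent
FA1,pasting_temperature,decrease,100,-0.83
FA1,stem_number,increase,100,31.99
FA1,stem_diameter,increase,0,-1.34
FA1,tuber_number,increase,100,16.51
FA1,ash_content,increase,100,7.03
FA2,pasting_time,decrease,100,-3.19
FA2,holding_strength,increase,0,-26.31
FA2,breakdown_value,increase,100,39.72
FA2,final_paste_viscosity,increase,0,-3.33
FA3,peel_loss,decrease,100,-9.53
FA3,starch_yield,increase,100,12.30
FA3,flour_yield,increase,100,6.74
FA4,yam_mosaic_virus,decrease,100,-15.70
FA4,leaf_chlorophyll,increase,100,0.48
FA4,tuber_yield,increase,100,16.43
FA5,dry_matter,increase,100,4.71
FA5,peak_viscosity,increase,100,9.28
FA5,protein_content,increase,100,3.73
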