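variable,level,exposed_case,exposed_control,unexposed_case,unexposed_control,or_printed,ci_low_printed,ci_high_printed,counts_consistent
sex,Male,39,65,43,70,0.98,0.56,1.69,TRUE
smoking,Yes,22,39,60,96,0.90,0.49,1.67,TRUE
cea,>5.0,15,21,67,114,1.22,0.59,2.52,TRUE
scca,>1.5,3,1,79,134,0.82,0.41,1.64,FALSE
nse,>17.0,30,43,52,92,1.23,0.69,2.20,TRUE
cyfra,>3.3,15,29,67,106,0.82,0.41,1.64,TRUE
lobulation,Present,74,121,8,14,1.07,0.43,2.67,TRUE
spiculation,Present,27,42,55,93,1.09,0.60,1.96,TRUE
bronchial_cutoff,Present,21,14,61,121,2.98,1.42,6.25,TRUE
air_bronchogram,Present,29,58,53,77,0.73,0.41,1.28,TRUE
vacuole,Present,27,39,55,96,1.21,0.67,2.18,TRUE
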