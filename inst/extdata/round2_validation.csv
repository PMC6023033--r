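cid,predicted_ic50_um,experimental_ic50_um,active,weak_activity
827004,0.30,3.04,TRUE,FALSE
4957387,4.27,32.9,TRUE,FALSE
898930,26.01,5.54,TRUE,FALSE
17178134,7.21,23.1,TRUE,FALSE
17178138,33.44,42.6,TRUE,FALSE
17131127,23.71,,FALSE,TRUE
834536,1.66,,FALSE,TRUE
693001,0.43,,FALSE,TRUE
792914,2.05,,FALSE,TRUE
570059,4.20,,FALSE,TRUE
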