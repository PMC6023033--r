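cid,predicted_ic50_um,experimental_ic50_um,active,weak_activity
17178137,21.9,11.0,TRUE,FALSE
4951143,6.77,19.1,TRUE,FALSE
2986934,1.18,0.34,TRUE,FALSE
710644,4.36,1.09,TRUE,FALSE
5146207,10.9,,FALSE,TRUE
807111,8.88,,FALSE,TRUE
1107361,11.2,,FALSE,FALSE
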