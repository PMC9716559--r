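{"format":"registercheck-classifier","formatVersion":1,"featureNames":["Accuracy","FPrate","smooth_Sensitivity","smooth_wRMSD","Z_Accuracy","Z_Sensitivity","Z_wRMSD","acc","ss_helix","ss_sheet","ss_coil"],"center":[0.94394591800333,0.00748977732753783,0.0798550701054524,3.89299083868516,0.0992701945285548,-0.0202854857066663,0.0774220798806555,0.330693618846213,0.480886850152905,0.134556574923547,0.384556574923547],"scale":[0.141932323948727,0.00980600537321902,0.112523891630155,1.69275365743802,0.933619411060707,0.74441166195137,0.957052665028136,0.169657496202402,0.499825655337544,0.341379848675124,0.486676377654901],"weights":[1.69826526048978,0.129533101278628,-0.143204722646761,2.36117930974447,0.0235703535835214,-0.14405881740796,0.164316353435351,-0.561997689700695,-0.0573225063911456,-0.0694620781170446,0.107595551054973],"bias":0.316111054470753,"calibration":{"a":-1.09973067998037,"b":0.07969478878206},"metadata":{"seed":1,"cost":11.319308413475,"balanced":false,"nIter":200,"cvFolds":5,"searchScore":0.82110980622431,"nSupport":613,"version":"0.1.0"}}
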