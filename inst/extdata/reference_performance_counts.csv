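split,model,tp,fn,tn,fp
training,habitat,64,9,107,12
training,radiomic,61,12,100,19
training,radiological,58,15,90,29
validation,habitat,29,5,42,6
validation,radiomic,26,8,40,8
validation,radiological,24,10,35,13
external_test,habitat,13,2,20,4
external_test,radiomic,11,4,19,5
external_test,radiological,10,5,17,7
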