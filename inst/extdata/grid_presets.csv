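name,x_cm,y_cm
narrow,2.2,-4.4
narrow,5.9,-4.4
narrow,9.6,-4.4
narrow,13.3,-4.4
narrow,2.2,-1.5
narrow,5.9,-1.5
narrow,9.6,-1.5
narrow,13.3,-1.5
narrow,2.2,1.5
narrow,5.9,1.5
narrow,9.6,1.5
narrow,13.3,1.5
narrow,2.2,4.4
narrow,5.9,4.4
narrow,9.6,4.4
narrow,13.3,4.4
wide,5.6,-2.6
wide,11.1,-2.6
wide,16.7,-2.6
wide,22.2,-2.6
wide,5.6,-1.1
wide,11.1,-1.1
wide,16.7,-1.1
wide,22.2,-1.1
wide,5.6,1.1
wide,11.1,1.1
wide,16.7,1.1
wide,22.2,1.1
wide,5.6,2.6
wide,11.1,2.6
wide,16.7,2.6
wide,22.2,2.6
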