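responder_a,responder_b,rho,p
radiology,emergency_neurology,1,0.040
radiology,emergency,1,0.040
ear_surgery,neurology,1,0.040
emergency_neurology,emergency,1,0.040
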