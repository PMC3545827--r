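responder_a,responder_b,rho,p
radiology,ear_surgery,0.73,0.004
radiology,emergency_neurology,0.82,0.001
radiology,emergency,0.77,0.002
ear_surgery,neurology,0.86,0.000
ear_surgery,emergency_neurology,0.74,0.003
ear_surgery,emergency,0.61,0.018
emergency_neurology,emergency,0.90,0.000
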