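node_id,responder_id,CR
performance,radiology,0.00
performance,ear_surgery,0.04
performance,neurology,0.03
performance,emergency_neurology,0.00
performance,emergency,0.01
safety,radiology,0.00
safety,ear_surgery,0.00
safety,neurology,0.00
safety,emergency_neurology,0.01
safety,emergency,0.03
usability,radiology,0.10
usability,ear_surgery,0.01
usability,neurology,0.00
usability,emergency_neurology,0.03
usability,emergency,0.00
technical,radiology,0.00
technical,ear_surgery,0.00
technical,neurology,0.00
technical,emergency_neurology,0.03
technical,emergency,0.00
goal,radiology,0.01
goal,ear_surgery,0.07
goal,neurology,0.06
goal,emergency_neurology,0.04
goal,emergency,0.02
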