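responder_id,category_id,CW
radiology,performance,0.22
radiology,safety,0.48
radiology,usability,0.19
radiology,technical,0.11
ear_surgery,performance,0.44
ear_surgery,safety,0.34
ear_surgery,usability,0.14
ear_surgery,technical,0.08
neurology,performance,0.39
neurology,safety,0.29
neurology,usability,0.22
neurology,technical,0.10
emergency_neurology,performance,0.19
emergency_neurology,safety,0.57
emergency_neurology,usability,0.17
emergency_neurology,technical,0.08
emergency,performance,0.18
emergency,safety,0.60
emergency,usability,0.13
emergency,technical,0.09
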