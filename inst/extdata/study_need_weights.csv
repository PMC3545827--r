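responder_id,category_id,need_id,GW,LW
radiology,performance,spatial_resolution,0.07,0.32
radiology,performance,speed_run,0.10,0.46
radiology,performance,processing_software,0.05,0.22
radiology,safety,radiation_dose,0.16,0.33
radiology,safety,patient_monitoring,0.16,0.33
radiology,safety,contrast_medium,0.16,0.33
radiology,usability,personnel_education,0.13,0.69
radiology,usability,user_friendly_gui,0.04,0.23
radiology,usability,interoperability,0.02,0.08
radiology,technical,technical_assistance,0.04,0.33
radiology,technical,maintenance,0.04,0.33
radiology,technical,data_storing,0.04,0.33
ear_surgery,performance,spatial_resolution,0.28,0.64
ear_surgery,performance,speed_run,0.05,0.11
ear_surgery,performance,processing_software,0.11,0.26
ear_surgery,safety,radiation_dose,0.11,0.33
ear_surgery,safety,patient_monitoring,0.11,0.33
ear_surgery,safety,contrast_medium,0.11,0.33
ear_surgery,usability,personnel_education,0.07,0.52
ear_surgery,usability,user_friendly_gui,0.03,0.18
ear_surgery,usability,interoperability,0.04,0.30
ear_surgery,technical,technical_assistance,0.03,0.33
ear_surgery,technical,maintenance,0.03,0.33
ear_surgery,technical,data_storing,0.03,0.33
neurology,performance,spatial_resolution,0.19,0.48
neurology,performance,speed_run,0.04,0.11
neurology,performance,processing_software,0.16,0.41
neurology,safety,radiation_dose,0.10,0.33
neurology,safety,patient_monitoring,0.10,0.33
neurology,safety,contrast_medium,0.10,0.33
neurology,usability,personnel_education,0.07,0.32
neurology,usability,user_friendly_gui,0.05,0.22
neurology,usability,interoperability,0.10,0.46
neurology,technical,technical_assistance,0.02,0.22
neurology,technical,maintenance,0.03,0.32
neurology,technical,data_storing,0.05,0.46
emergency_neurology,performance,spatial_resolution,0.08,0.43
emergency_neurology,performance,speed_run,0.08,0.43
emergency_neurology,performance,processing_software,0.03,0.14
emergency_neurology,safety,radiation_dose,0.08,0.14
emergency_neurology,safety,patient_monitoring,0.33,0.58
emergency_neurology,safety,contrast_medium,0.16,0.28
emergency_neurology,usability,personnel_education,0.08,0.48
emergency_neurology,usability,user_friendly_gui,0.02,0.11
emergency_neurology,usability,interoperability,0.07,0.41
emergency_neurology,technical,technical_assistance,0.05,0.66
emergency_neurology,technical,maintenance,0.01,0.16
emergency_neurology,technical,data_storing,0.01,0.18
emergency,performance,spatial_resolution,0.05,0.30
emergency,performance,speed_run,0.09,0.52
emergency,performance,processing_software,0.03,0.18
emergency,safety,radiation_dose,0.11,0.18
emergency,safety,patient_monitoring,0.40,0.66
emergency,safety,contrast_medium,0.10,0.16
emergency,usability,personnel_education,0.04,0.33
emergency,usability,user_friendly_gui,0.04,0.33
emergency,usability,interoperability,0.04,0.33
emergency,technical,technical_assistance,0.04,0.46
emergency,technical,maintenance,0.03,0.32
emergency,technical,data_storing,0.02,0.22
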