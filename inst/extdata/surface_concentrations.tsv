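metabolite	group	mean_conc_mg_per_l	detected
adipic acid	axenic	2.4	TRUE
adipic acid	nonaxenic	587.5	TRUE
ethylmalonic acid	axenic	0.01	TRUE
ethylmalonic acid	nonaxenic	0.0	TRUE
glutaric acid	axenic	8.7	TRUE
glutaric acid	nonaxenic	63.7	TRUE
hypoxanthine	axenic	0.0	TRUE
hypoxanthine	nonaxenic	0.001	TRUE
indoleacetic acid	axenic	11.9	TRUE
indoleacetic acid	nonaxenic	191.2	TRUE
ketoisocaproic acid	axenic	4.9	TRUE
ketoisocaproic acid	nonaxenic	66.1	TRUE
kynurenic acid	axenic	0.54	TRUE
kynurenic acid	nonaxenic	0.1	TRUE
phenyllactic acid	axenic	14.0	TRUE
phenyllactic acid	nonaxenic	6.3	TRUE
picolinic acid	axenic	0.21	TRUE
picolinic acid	nonaxenic	0.18	TRUE
thymine	axenic	0.0	FALSE
thymine	nonaxenic	0.0	FALSE
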