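name	cas	formula	monoisotopic_mass	is_nutrient
adipic acid	124-04-9	C6H10O4	146.057909	FALSE
ethylmalonic acid	601-75-2	C5H8O4	132.042259	FALSE
glutaric acid	110-94-1	C5H8O4	132.042259	FALSE
hypoxanthine	68-94-0	C5H4N4O	136.038511	FALSE
indoleacetic acid	87-51-4	C10H9NO2	175.063329	FALSE
ketoisocaproic acid	816-66-0	C6H10O3	130.062994	FALSE
kynurenic acid	492-27-3	C10H7NO3	189.042593	FALSE
phenyllactic acid	828-01-3	C9H10O3	166.062994	FALSE
picolinic acid	98-98-6	C6H5NO2	123.032028	FALSE
thymine	65-71-4	C5H6N2O2	126.042927	FALSE
l-leucine	61-90-5	C6H13NO2	131.094629	TRUE
l-sorbose	87-79-6	C6H12O6	180.063388	TRUE
l-tyrosine	60-18-4	C9H11NO3	181.073893	TRUE
l-valine	72-18-4	C5H11NO2	117.078979	TRUE
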