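pathway	exposure	mediator	total_effect	two_step_effect	two_step_prop	mvmr_effect	mvmr_prop
microbiota-metabolite	OTU99_5_Sutterella_abundance	alanine	-6.89E-04	-1.45E-04	21.10	7.73E-05	NA
microbiota-metabolite	TestASV_4_Alistipes_prevalence	3-methyl-2-oxovalerate	6.76E-04	1.67E-04	24.73	-4.87E-06	NA
microbiota-metabolite	OTU99_78_Clostridiales_prevalence	3-methyl-2-oxovalerate	-4.92E-04	-2.86E-04	58.22	-2.40E-04	48.70
microbiota-metabolite	OTU97_69_Clostridiales_prevalence	3-methyl-2-oxovalerate	-4.93E-04	-2.86E-04	58.07	-2.61E-04	52.89
microbiota-metabolite	TestASV_32_Ruminococcaceae_prevalence	ADSGEGDFXAEGGGVR	-2.45E-04	9.66E-06	NA	-5.50E-05	22.44
microbiota-metabolite	TestASV_32_Ruminococcaceae_prevalence	X-11793-oxidized-bilirubin	-2.45E-04	1.81E-05	NA	-8.68E-05	35.40
microbiota-cytokine	TestASV_6_Subdoligranulum_abundance	TSG-6	-7.30E-04	-5.65E-05	7.75	1.23E-04	NA
microbiota-cytokine	G_Bacteroidetes_prevalence	TSG-6	4.60E-04	-4.50E-05	NA	2.37E-05	5.16
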