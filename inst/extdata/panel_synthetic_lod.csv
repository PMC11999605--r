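"metabolite","pathway","lod"
"12-HETE","12-LOX",0.1
"Tetranor-12-HETE","12-LOX",0.006
"12-oxoETE","12-LOX",0.005
"14-HDoHE","12-LOX",0.03
"Maresin 1","12-LOX",0.005
"12-HEPE","12-LOX",0.02
"15-HETE","15-LOX",0.06
"15-oxoETE","15-LOX",0.001
"8-HETE","15-LOX",0.009
"14,15-LTC4","15-LOX",0.005
"8,15-diHETE","15-LOX",0.005
"LXA4","15-LOX",0.005
"17-HDoHE","15-LOX",0.04
"10,17-DiHDoHE","15-LOX",0.005
"7,17-dihydroxy-DPA","15-LOX",0.005
"15-HEPE","15-LOX",0.006
"13-HODE","15-LOX",0.9
"5-HETE","5-LOX",0.03
"5-oxoETE","5-LOX",0.002
"LTE4","5-LOX",2e-04
"20-carboxy-LTB4","5-LOX",0.005
"20-hydroxy-LTB4","5-LOX",0.005
"LTB4","5-LOX",0.005
"LTC4","5-LOX",0.005
"LTD4","5-LOX",0.005
"5,15-diHETE","5-LOX/15-LOX",0.005
"4-HDoHE","5-LOX",0.02
"7-HDoHE","5-LOX",0.003
"RvD2","5-LOX/15-LOX",0.005
"5-HEPE","5-LOX",0.006
"RvE1","5-LOX",0.005
"11-HETE","COX",0.008
"12-HHT","COX",0.05
"6-keto-PGF1a","COX",0.003
"PGA2","COX",0.001
"PGE2","COX",0.02
"PGF2a","COX",0.006
"Tetranor-PGEM","COX",0.02
"TXB2","COX",0.02
"11-dhTXB2","COX",0.005
"15-deoxy-PGJ2","COX",0.005
"6,15-diketo-13,14-dihydro-PGF1a","COX",0.005
"PGD2","COX",0.005
"PGF1a","COX",0.003
"17-keto-DPA","COX",0.004
"PGF3a","COX",0.002
"11-HEPE","COX",0.005
"PGD3","COX",0.005
"PGE3","COX",0.005
"TXB3","COX",0.005
"9-HODE","COX",0.4
"9-HpODE","COX",0.005
"11,12-DHET","CYP",0.06
"11,12-EET","CYP",6e-04
"14,15-DHET","CYP",0.07
"18-HETE","CYP",0.03
"20-HETE","CYP",0.005
"14,15-diHETE","CYP",0.02
"12,13-diHOME","CYP",0.9
"12,13-EpOME","CYP",0.08
"9,10-diHOME","CYP",0.3
"18-HEPE","CYP/COX",0.005
"5-iso-PGF2a","AUTOX",0.01
"9-HETE","AUTOX",0.006
"10-HDoHE","AUTOX",0.006
"9-HEPE","AUTOX",8e-04
"8-HEPE","AUTOX",0.005
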