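module	pathway	p
FOXO3_NM	03050~Proteasome	0.0342
FOXO3_NM	05213~Endometrial cancer	0.0213
FOXO3_NM	05223~Non-small cell lung cancer	0.0221
TP53_NM	04110~Cell cycle	0.039
TP53_NM	04115~p53 signaling pathway	0.0212
TP53_NM	04210~Apoptosis	0.027
TP53_NM	04310~Wnt signaling pathway	0.0459
TP53_NM	04722~Neurotrophin signaling pathway	0.0384
TP53_NM	05014~Amyotrophic lateral sclerosis (ALS)	0.0163
TP53_NM	05210~Colorectal cancer	0.0191
TP53_NM	05212~Pancreatic cancer	0.0215
TP53_NM	05213~Endometrial cancer	0.016
TP53_NM	05214~Glioma	0.02
TP53_NM	05215~Prostate cancer	0.0273
TP53_NM	05216~Thyroid cancer	0.009
TP53_NM	05217~Basal cell carcinoma	0.0169
TP53_NM	05218~Melanoma	0.0218
TP53_NM	05219~Bladder cancer	0.013
TP53_NM	05220~Chronic myeloid leukemia	0.0224
TP53_NM	05222~Small cell lung cancer	0.0258
TP53_NM	05223~Non-small cell lung cancer	0.0166
hsa_miR_16_M	04330~Notch signaling pathway	0.024
hsa_miR_16_M	04370~VEGF signaling pathway	0.0386
hsa_miR_16_M	04662~B cell receptor signaling pathway	0.0381
hsa_let_7e_M	04210~Apoptosis	0.0181
hsa_let_7e_M	04722~Neurotrophin signaling pathway	0.0258
hsa_miR_30a_M	04140~Regulation of autophagy	0.0425
hsa_miR_30a_M	04144~Endocytosis	0.0264
STAT1_M	03440~Homologous recombination	0.0086
STAT1_M	04062~Chemokine signaling pathway	0.0385
STAT1_M	04620~Toll-like receptor signaling pathway	0.0209
STAT1_M	04630~Jak-STAT signaling pathway	0.0317
STAT1_M	05212~Pancreatic cancer	0.0144
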