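icd10	phecode	label
E20	252.2	Hypoparathyroidism
E209	252.2	Hypoparathyroidism, unspecified
E208	252.2	Other hypoparathyroidism
E835	275.5	Disorders of calcium/phosphorus metabolism
E8351	275.5	Hypocalcemia
E8352	275.5	Hypercalcemia
E8358	275.5	Other disorders of calcium metabolism
R290	350.1	Tetany
R202	687.4	Paresthesia of skin
G40	345	Epilepsy, recurrent seizures, convulsions
G400	345.1	Generalized nonconvulsive epilepsy
G401	345.1	Generalized convulsive epilepsy
G403	345.1	Generalized idiopathic epilepsy
G409	345	Epilepsy, unspecified
G4090	345	Epilepsy, unspecified, not intractable
I10	401.1	Essential hypertension
E119	250.2	Type 2 diabetes
E780	272.1	Hypercholesterolemia
J459	495	Asthma
K219	530.11	GERD
M545	760	Low back pain
F329	296.2	Depression
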