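patient	gender	age_years	severe_developmental_delay	speech_impairment	ataxia_unsteady_gait	happy_demeanor	stereotypies	microcephaly	seizures	abnormal_eeg	other_frequent_features	additional_features
1	M	14	+	+ (5-10 words)	+	+	+	-	+	+	Sleep disorder, hypotonia	Congenital torticolis, bruxism, aggressive behavior
2	F	19	+	+ (less than 5 words)	-	+	+	-	+	+	Sleep disorder, feeding problems, kyphoscoliosis	Aggressive behavior
3	F	12	+	+ (Absent speech)	+	-	+	-	+	+	Hypotonia	Aggressive behavior
4	F	9	+	+ (Absent speech)	+	+	+	+ (Relative)	-	+	Hypotonia, feeding problems	-
5	F	20	+	+ (5-10 words)	+	+	-	-	-	+	-	Dental anomalies, auto and hetero-aggressive behavior
6	F	18	+	+ (Absent speech)	-	+	-	+ (Relative)	+	-	Scoliosis	-
7	M	15	+	+ (less than 5 words)	+	+	+	-	+	+	Feeding problems, wide mouth, hypotonia	Sparse scalp hair, hypertricosis in the back and hypoplasia of the corpus callosum, hypoplasic 5th fingernail, auto and hetero-aggressive behavior
8	F	14	+	+ (More than 20 words)	+	+	-	+	-	-	Hypotonia	Cerebellar atrophy
9	M	38	+	+ (Absent speech)	+	+	+	+ (Relative)	+	+	Hypotonia, feeding problems (esophageal reflux), sleep disorder	Dental anomalies, bruxism, episodic hyperventilation
10	M	7	+	+ (less than 5 words)	-	+	-	+ (Relative)	-	-	Wide spaced teeth, brachycephaly	Truncal obesity, short stature
11	F	14	+	+ (less than 5 words)	-	+	+	+ (Relative)	+	-	Feeding problems (dysphagia)	-
12	M	24	+	+ (5-10 words)	-	+	+	+	+	NA	Strabismus, sleep disorder, kyphoscoliosis	Hypoplasia of the corpus callosum, abnormal behavior, hypothyroidism, bruxism
13	M	9	+	+ (Absent speech)	+	+	+	+ (Relative)	+	-	Sleep disorder, hypotonia	Episodic hyperventilation, mild subcortical atrophy
14	M	13	+	+ (Absent speech)	+	+	+	-	+	+	Sleep disorder, wide-spaced teeth	Myoclonic atonic seizures, bruxism
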