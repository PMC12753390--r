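region	channel1	channel2	channel3	channel4	channel5
Frontal Pole	Fpz	Fp1	Fp2	AFz	AF4
Superior Frontal Gyrus	Fz	F1	F2	FCz	AFz
Middle Frontal Gyrus	F3	F4	F5	F6	AF3
Inferior Frontal Gyrus, pars triangularis	F7	F8	FT7	F5	F6
Precentral Gyrus	Cz	C1	C2	FCz	FC1
Postcentral Gyrus	CPz	CP1	CP2	C1	C2
Superior Parietal Lobule	Pz	P1	P2	CPz	CP1
Supramarginal Gyrus, anterior division	CP5	CP6	P5	P6	TP7
Angular Gyrus	P3	P4	P5	P6	PO3
Superior Temporal Gyrus, anterior division	T7	T8	FT7	FT8	TP7
Middle Temporal Gyrus, posterior division	TP7	TP8	P7	P8	T7
Lateral Occipital Cortex, inferior division	PO7	PO8	O1	O2	PO3
Cuneal Cortex	POz	PO3	PO4	Oz	Pz
Occipital Pole	Oz	O1	O2	POz	PO7
Insular Cortex	T7	T8	FT7	FT8	C5
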