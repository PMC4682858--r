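label	promoter	gene	tf	padj	coef
generic	chr2:238395772..238395830,-	NA	FALSE	0.995	-0.03
generic	chr3:124732396..124732408,-	HEG1	FALSE	0.989	-0.01
generic	chr12:132379245..132379256,+	ULK1	FALSE	0.985	-0.1
generic	chr20:46415341..46415360,-	SULF2	FALSE	0.985	-0.05
generic	chr10:99185961..99185987,+	PGAM1	FALSE	0.969	0.03
generic	chr16:67515264..67515316,+	NA	FALSE	0.964	0.02
generic	chr19:48972612..48972632,+	CYTH2	FALSE	0.962	-0.03
generic	chr9:34665595..34665628,+	NA	FALSE	0.961	-0.06
generic	chr3:50192499..50192534,+	SEMA3F	FALSE	0.960	-0.03
generic	chr12:16035307..16035352,+	STRAP	FALSE	0.960	0.02
stimulus_specific	chr10:54074033..54074050,+	DKK1	FALSE	6.38E-22	0.04
stimulus_specific	chr6:43737939..43737956,+	VEGFA	FALSE	6.23E-22	0.05
stimulus_specific	chr2:106015491..106015518,-	FHL2	FALSE	5.55E-22	0.06
stimulus_specific	chr14:69445991..69446029,-	ACTN1	FALSE	4.91E-22	0.04
stimulus_specific	chr7:143078379..143078454,+	ZYX	FALSE	2.78E-22	0.09
stimulus_specific	chr1:86046433..86046453,+	CYR61	FALSE	7.29E-24	-0.05
stimulus_specific	chr21:40177845..40177863,+	ETS2	TRUE	2.65E-24	-0.02
stimulus_specific	chr3:5021113..5021180,+	BHLHE40	TRUE	2.65E-24	0.03
stimulus_specific	chrX:153602991..153603011,-	FLNA	FALSE	2.15E-29	0.09
stimulus_specific	chr10:75757863..75757897,+	VCL	FALSE	7.46E-30	-0.01
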