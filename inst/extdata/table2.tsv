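label	promoter	gene	tf	padj	coef
stimulus_specific	chr17:39675131..39675148,-	KRT15	FALSE	0.0000	0.06
stimulus_specific	chr16:28835766..28835827,+	N/A	FALSE	0.0002	0.09
stimulus_specific	chr8:119964115..119964132,-	TNFRSF11B	FALSE	0.0002	0.18
stimulus_specific	chr2:120980665..120980750,-	TMEM185B	FALSE	0.0008	0.04
stimulus_specific	chr11:2950642..2950658,-	PHLDA2	FALSE	0.0014	0.1
stimulus_specific	chr10:112257656..112257671,+	DUSP5	FALSE	0.0015	-0.02
stimulus_specific	chr5:137801160..137801176,+	EGR1	TRUE	0.0053	-0.21
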