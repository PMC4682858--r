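gene	tf	n_generic	generic_promoters	n_specific	specific_promoters
EGR1	TRUE	4	chr5:137804130..137804156,+//chr5:137804357..137804390,+//chr5:137804405..137804444,+//chr5:137804484..137804498,+	3	chr5:137800878..137800898,+//chr5:137800912..137800941,+//chr5:137801160..137801176,+
FOS	TRUE	2	chr14:75746579..75746605,+//chr14:75746705..75746720,+	5	chr14:75745523..75745537,+//chr14:75746722..75746777,+//chr14:75746781..75746799,+//chr14:75747250..75747267,+//chr14:75747296..75747329,+
ELOVL1	FALSE	2	chr1:43832006..43832027,-//chr1:43833263..43833293,-	1	chr1:43833628..43833703,-
PLEC	FALSE	2	chr8:145027973..145027992,-//chr8:145047688..145047704,-	1	chr8:145013711..145013786,-
HIST1H2BC	FALSE	1	chr6:26199709..26199720,+	3	chr6:26124147..26124168,-//chr6:26199737..26199754,+//chr6:26273152..26273175,+
HIST1H2BE	FALSE	1	chr6:26199709..26199720,+	3	chr6:26124147..26124168,-//chr6:26199737..26199754,+//chr6:26273152..26273175,+
HIST1H2BF	FALSE	1	chr6:26199709..26199720,+	3	chr6:26124147..26124168,-//chr6:26199737..26199754,+//chr6:26273152..26273175,+
HIST1H2BG	FALSE	1	chr6:26199709..26199720,+	3	chr6:26124147..26124168,-//chr6:26199737..26199754,+//chr6:26273152..26273175,+
HIST1H2BI	FALSE	1	chr6:26199709..26199720,+	3	chr6:26124147..26124168,-//chr6:26199737..26199754,+//chr6:26273152..26273175,+
SMAD3	TRUE	1	chr15:67418119..67418162,+	3	chr15:67358163..67358192,+//chr15:67418047..67418093,+//chr15:67418177..67418204,+
HIST1H3A	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3B	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3C	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3D	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3E	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3F	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3G	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3H	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3I	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
HIST1H3J	FALSE	1	chr6:26197500..26197521,-	2	chr6:26020672..26020689,+//chr6:27840112..27840133,-
METTL7B	FALSE	1	chr12:56075495..56075509,+	2	chr12:56075432..56075444,+//chr12:56075512..56075532,+
ATP1B1	FALSE	1	chr1:169075919..169075940,+	1	chr1:169075554..169075571,+
BBC3	FALSE	1	chr19:47734425..47734445,-	1	chr19:47734448..47734466,-
BRIP1	TRUE	1	chr17:59940830..59940897,-	1	chr17:59940813..59940828,-
DDIT4	FALSE	1	chr10:74034090..74034110,+	1	chr10:74033672..74033688,+
FAM207A	FALSE	1	chr21:46359889..46359902,+	1	chr21:46359907..46359962,+
FAM83H	FALSE	1	chr8:144815895..144815912,-	1	chr8:144815914..144815961,-
FOXA1	TRUE	1	chr14:38065203..38065215,-	1	chr14:38064495..38064506,-
GRB7	FALSE	1	chr17:37894179..37894202,+	1	chr17:37894570..37894614,+
GREB1	FALSE	1	chr2:11679938..11679951,+	1	chr2:11679963..11679986,+
IFIT5	FALSE	1	chr10:91174314..91174403,+	1	chr10:91174486..91174528,+
IRF2BPL	FALSE	1	chr14:77493956..77493999,-	1	chr14:77494141..77494170,-
KLF6	FALSE	1	chr10:3827371..3827386,-	1	chr10:3827389..3827408,-
MBTPS1	FALSE	1	chr16:84150492..84150558,-	1	chr16:84150410..84150456,-
PRR15L	FALSE	1	chr17:46035113..46035124,-	1	chr17:46035187..46035260,-
S100A16	FALSE	1	chr1:153585456..153585532,-	1	chr1:153585571..153585629,-
WARS	FALSE	1	chr14:100841675..100841691,-	1	chr14:100841940..100841958,-
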