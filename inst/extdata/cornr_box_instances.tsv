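accession	motif	score	pvalue	elm_tp
O75376	LADHICQII	0.715	0.048	TRUE
P05160	LTFIIILII	0.680	0.969	FALSE
Q9Y618	LEAIIRKAL	0.557	0.026	TRUE
Q9UBF1	LLIIILSVI	0.543	1	FALSE
Q96BZ9	LIDIILLIL	0.520	0.208	FALSE
Q8NI22	LINIIDGVL	0.486	0.214	FALSE
Q07325	LLGIILLVL	0.467	0.396	FALSE
Q5SVZ6	LKLIIENIL	0.434	0.329	FALSE
Q96AH8	LKLIIVGAI	0.425	0.75	FALSE
Q9HAU8	LTFIISSIL	0.401	0.436	FALSE
Q9NRU3	LEDIIEEII	0.384	0.393	FALSE
P53618	LMTIIRFVL	0.363	0.321	FALSE
O75376	LEDIIRKAL	0.362	0.044	TRUE
Q8IWF6	LRTHIDAII	0.350	0.197	FALSE
Q8NHV5	LFFIIMGII	0.341	1	FALSE
Q9UPM8	LRLHIIEII	0.338	0.3	FALSE
Q9Y618	LAQHISEVI	0.335	0.055	TRUE
Q96N64	LDHIIEDAL	0.333	0.562	FALSE
O95477	LSRIIWKAL	0.332	0.614	FALSE
O00273	LASHILTAL	0.327	0.546	FALSE
Q7Z3J2	LQLIIKKVI	0.325	0.096	FALSE
Q09161	LNYHIVEVI	0.306	0.799	FALSE
Q08AE8	LGIIIYKAL	0.294	0.164	FALSE
Q8TDJ6	LNNHIHDIL	0.287	0.115	FALSE
P07384	LYQIILKAL	0.283	0.518	FALSE
Q5MIZ7	LYEIIRGIL	0.282	0.295	FALSE
Q8TDR0	LHDIITEVI	0.282	0.43	FALSE
Q96PN6	LKNIITVVI	0.276	0.645	FALSE
Q8TCG5	LGQHIEDAL	0.274	0.294	FALSE
Q6ZMV5	LYEIIKGIL	0.272	0.321	FALSE
Q8IX04	LQYIITNVL	0.267	0.539	FALSE
Q93100	LVIHIGWII	0.267	0.81	FALSE
Q8TDL5	LKNIITEII	0.267	0.617	FALSE
Q9C093	LVDIIVNAI	0.266	0.086	FALSE
Q7RTX7	LARIIRVIL	0.262	0.345	FALSE
Q9UIA9	LVYIIGAVI	0.257	0.104	FALSE
Q8NEG5	LCKHICWVL	0.257	0.114	FALSE
Q9Y6X3	LLGHIFYVL	0.232	0.885	FALSE
Q8IZQ1	LAQIILDAI	0.221	0.708	FALSE
P35556	LNNHIRYVI	0.216	0.145	FALSE
Q14185	LLSHILEVL	0.209	0.067	FALSE
O95801	LKAIIRGAL	0.199	0.732	FALSE
A6NHC0	LYQIIRKAL	0.193	0.817	FALSE
P56192	LGNIIGCVL	0.189	0.542	FALSE
A6NES4	LTSIIVAVI	0.184	1	FALSE
O95714	LCTHIGDIL	0.183	0.034	FALSE
Q8NF50	LVGIILDAL	0.182	0.629	FALSE
O95450	LGAHINVVL	0.174	0.364	FALSE
Q8N485	LRHIIAQVL	0.174	0.898	FALSE
Q8TCG1	LKMHIAKIL	0.173	0.55	FALSE
Q6R327	LDHIIQKAI	0.162	0.067	FALSE
Q5T215	LCGIIRGAL	0.160	0.131	FALSE
Q8WZ26	LSTHICVVL	0.159	1	FALSE
P51124	LTFHIKAAI	0.158	0.658	FALSE
Q99698	LNSIIDQAL	0.156	0.672	FALSE
Q562E7	LSDITYYVY	0.156	0.94	FALSE
Q9UJ70	LGRHIVAVL	0.153	0.136	FALSE
Q0VDD8	LDKHIKSAI	0.152	1	FALSE
Q8N1T3	LFGIIASVL	0.151	0.326	FALSE
P17655	LFKIIQKAL	0.148	0.804	FALSE
P52743	LHVIIDFIL	0.147	1	FALSE
Q6PGP7	LEDIIGFAL	0.146	0.128	FALSE
Q13572	LLNHIATVL	0.134	0.551	FALSE
O15072	LGVHINVVL	0.128	0.362	FALSE
Q8WXS8	LGVHINIAL	0.110	0.585	FALSE
Q9UG01	LVEHITAAL	0.107	0.082	FALSE
P30307	LGGHIQGAL	0.061	0.072	FALSE
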