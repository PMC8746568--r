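# MS2 fragment peaks as printed in the published table: m/z, relative
# intensity (% of base peak) and, where printed, the assigned ion
# composition. "-" marks peaks printed without a composition.
feature_id	mz	intensity	printed_formula
M0_pos	777.22113	100	C34H42O19Na
M0_pos	409.11023	21.58	C17H22O10Na
M0_pos	391.09967	6.09	C17H20O9Na
M0_neg	205.05049	100	C11H9O4
M0_neg	190.02710	88.42	C10H6O4
M0_neg	175.00372	28.26	C9H3O4
M0_neg	547.16614	12.27	C23H31O15
M0_neg	164.04791	8.76	C9H8O3
M0_neg	223.06189	7.23	C11H11O5
M1_pos	571.16266	100	C23H32O15Na
M1_pos	409.10941	22.62	C17H22O10Na
M1_pos	391.10001	6.90	C17H20O9Na
M1_neg	205.05058	100	C11H9O4
M1_neg	190.02713	57.13	C10H6O4
M1_neg	175.00354	20.99	C9H3O4
M1_neg	547.16681	18.35	C23H31O15
M1_neg	223.06117	11.96	C11H11O5
M2_pos	181.04924	100	C9H9O4
M2_pos	227.09102	26.19	C11H15O5
M2_pos	209.08060	21.94	C11H13O4
M2_pos	167.07001	6.11	C9H11O3
M3_pos	85.06531	100	C5H9O
M3_pos	149.09598	63.70	C10H13O
M3_pos	191.10643	61.59	C12H15O2
M3_pos	209.11690	60.39	C12H17O3
M3_pos	227.12654	37.93	-
M4_neg	339.05457	100	C11H15O12
M4_neg	259.09747	57.77	C15H15O4
M4_neg	229.08693	55.89	C14H13O3
M4_neg	122.03733	9.81	C7H6O2
M4_neg	134.03729	7.20	C8H6O2
M4_neg	295.09653	5.07	C18H15O4
M5_pos	70.06594	100	-
M5_pos	245.11336	41.27	C13H18O3Na
M5_pos	227.10280	36.82	C13H16O2Na
M5_pos	277.11856	32.87	C15H15O2
M5_pos	249.12337	27.44	C16H18ONa
M5_pos	325.17694	26.45	C19H26O3Na
M5_pos	343.18710	24.09	C19H28O4Na
M5_pos	201.12357	21.03	C12H18ONa
M5_neg	321.04388	100	C11H13O11
M5_neg	241.08717	25.58	C15H13O3
M5_neg	322.04718	13.30	C18H10O6
M5_neg	294.13840	10.90	C23H18
M6_pos	167.07014	100	C9H11O3
M6_pos	177.05444	5.15	C10H9O3
M6_pos	209.08076	3.85	C11H13O4
M7_pos	207.06502	100	C11H11O4
M7_pos	175.03889	63.01	C10H7O3
M7_pos	192.04141	21.64	C10H8O4
M7_pos	149.02347	7.54	C8H5O3
M7_pos	164.04666	5.36	C9H8O3
M8_pos	243.08736	100	C11H15O6
M8_pos	172.08670	40.40	-
M8_pos	216.07651	29.79	-
M8_pos	198.06587	15.69	-
M8_pos	197.08096	0.46	C10H13O4
M9_pos	341.22040	100	-
M9_pos	238.19051	4.07	C13H27O2Na
M9_pos	205.08562	2.72	C11H9O4
M9_pos	323.09164	2.71	C19H15O5
M9_pos	191.07014	2.70	C11H11O3
M9_pos	107.08558	2.32	C8H11
M9_pos	163.07523	2.16	C10H11O2
M10_pos	395.28958	100	C25H40O2Na
M10_pos	377.27933	36.24	C25H38ONa
M10_pos	107.08579	9.68	C6H12Na
M10_pos	271.12012	5.33	C11H20O6Na
M10_pos	359.26834	5.17	C25H36Na
M10_neg	147.11789	100	-
M10_neg	371.17041	67.35	C18H27O8
M10_neg	209.11717	4.69	C12H17O3
M10_neg	179.05547	2.83	-
M10_neg	191.10738	2.68	-
M10_neg	149.04442	2.16	C5H9O5
M10_neg	293.94162	1.78	-
M10_neg	207.10025	1.73	-
M11_pos	395.20325	100	C19H32O7Na
M11_pos	203.05223	23.02	C6H12O6Na
M11_pos	201.03685	6.26	C6H10O6Na
M11_pos	217.15601	5.52	C13H22ONa
M11_pos	215.14053	4.39	C13H20ONa
M11_pos	121.10120	1.80	C9H13
M12_pos	241.16249	100	-
M12_pos	123.116687	25.31	C9H15
M12_pos	147.11676	13.58	C11H15
M13_pos	98.98458	100	-
M13_pos	251.08862	76.53	C11H16O5Na
M13_pos	251.12540	61.89	C12H20O4Na
M13_pos	141.09071	7.51	C6H14O2Na
M13_pos	167.08630	6.81	C11H12Na
M13_pos	173.13144	5.06	C11H18Na
M13_neg	227.12891	100	C12H19O4
M13_neg	183.13898	30.81	C11H19O2
M13_neg	165.12851	27.80	C11H17O
M13_neg	209.11829	25.19	C12H17O3
M14_neg	371.11700	100	C13H23O12
M14_neg	291.16016	66.46	C17H23O4
M14_neg	79.95737	30.93	-
M14_neg	247.17033	30.14	C16H23O2
M14_neg	371.24493	24.66	-
M14_neg	122.03730	17.26	-
M14_neg	123.04517	13.98	-
M14_neg	135.04510	13.06	-
M15_neg	223.11705	100	C9H19O6
M15_neg	122.10566	13.98	C9H14
M15_neg	179.12711	44.85	C8H19O
M16_pos	409.09137	100	C22H17O8
M16_pos	427.10205	98.04	C22H19O9
M16_pos	391.08096	72.55	C22H15O7
M16_pos	379.08099	71.11	C21H15O7
M16_pos	511.12332	50.98	C26H23O11
M16_pos	481.11246	50.12	C25H21O10
M16_pos	325.07050	40.00	C18H13O6
M16_pos	349.07037	33.57	C20H13O6
M16_pos	337.07034	24.35	C19H13O6
M16_pos	355.08121	23.50	C19H15O7
M16_neg	353.06680	100	-
M16_neg	443.09808	76.65	C22H19O10
M16_neg	473.10849	34.99	C23H21O11
M16_neg	725.19037	33.48	C32H37O19
M16_neg	545.12988	18.62	C26H25O13
M16_neg	413.08752	15.06	C21H17O9
M16_neg	407.07764	11.06	C22H15O8
M17_pos	127.03926	100	C6H7O3
M17_pos	189.08713	53.89	C12H13O2
M17_pos	156.07675	41.81	C8H12O3
M17_pos	155.08171	19.55	C12H11
M17_pos	213.09970	16.21	C7H17O7
M17_pos	159.07664	15.36	C11H11O
M17_neg	212.00232	100	-
M17_neg	217.01762	43.23	C4H9O10
M17_neg	80.96514	21.35	-
M17_neg	261.00748	17.73	C12H5O7
M17_neg	213.00554	10.55	C8H5O7
M17_neg	137.06081	10.27	C8H9O2
M18_pos	227.06352	100	C12H12O3Na
M18_pos	209.11656	71.14	C12H17O3
M19_neg	112.98559	100	-
M19_neg	323.22034	32.70	C19H31O4
M19_neg	255.23296	25.16	C16H31O2
M19_neg	391.20743	10.03	C29H27O
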