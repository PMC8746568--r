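BEGIN IONS
TITLE=M0_pos
PEPMASS=777.22101
CHARGE=1+
777.22113 100.0000
409.11023 21.5800
391.09967 6.0900
END IONS

BEGIN IONS
TITLE=M0_neg
PEPMASS=753.22528
CHARGE=1-
205.05049 100.0000
190.02710 88.4200
175.00372 28.2600
547.16614 12.2700
164.04791 8.7600
223.06189 7.2300
END IONS

BEGIN IONS
TITLE=M1_pos
PEPMASS=571.16290
CHARGE=1+
571.16266 100.0000
409.10941 22.6200
391.10001 6.9000
END IONS

BEGIN IONS
TITLE=M1_neg
PEPMASS=547.16669
CHARGE=1-
205.05058 100.0000
190.02713 57.1300
175.00354 20.9900
547.16681 18.3500
223.06117 11.9600
END IONS

BEGIN IONS
TITLE=M2_pos
PEPMASS=227.09128
CHARGE=1+
181.04924 100.0000
227.09102 26.1900
209.08060 21.9400
167.07001 6.1100
END IONS

BEGIN IONS
TITLE=M3_pos
PEPMASS=227.12766
CHARGE=1+
85.06531 100.0000
149.09598 63.7000
191.10643 61.5900
209.11690 60.3900
227.12654 37.9300
END IONS

BEGIN IONS
TITLE=M4_neg
PEPMASS=339.10873
CHARGE=1-
339.05457 100.0000
259.09747 57.7700
229.08693 55.8900
122.03733 9.8100
134.03729 7.2000
295.09653 5.0700
END IONS

BEGIN IONS
TITLE=M5_pos
PEPMASS=735.17440
CHARGE=1+
70.06594 100.0000
245.11336 41.2700
227.10280 36.8200
277.11856 32.8700
249.12337 27.4400
325.17694 26.4500
343.18710 24.0900
201.12357 21.0300
END IONS

BEGIN IONS
TITLE=M5_neg
PEPMASS=711.17834
CHARGE=1-
321.04388 100.0000
241.08717 25.5800
322.04718 13.3000
294.13840 10.9000
END IONS

BEGIN IONS
TITLE=M6_pos
PEPMASS=227.09129
CHARGE=1+
167.07014 100.0000
177.05444 5.1500
209.08076 3.8500
END IONS

BEGIN IONS
TITLE=M7_pos
PEPMASS=225.07570
CHARGE=1+
207.06502 100.0000
175.03889 63.0100
192.04141 21.6400
149.02347 7.5400
164.04666 5.3600
END IONS

BEGIN IONS
TITLE=M8_pos
PEPMASS=243.08733
CHARGE=1+
243.08736 100.0000
172.08670 40.4000
216.07651 29.7900
198.06587 15.6900
197.08096 0.4600
END IONS

BEGIN IONS
TITLE=M9_pos
PEPMASS=341.12158
CHARGE=1+
341.22040 100.0000
238.19051 4.0700
205.08562 2.7200
323.09164 2.7100
191.07014 2.7000
107.08558 2.3200
163.07523 2.1600
END IONS

BEGIN IONS
TITLE=M10_pos
PEPMASS=395.13052
CHARGE=1+
395.28958 100.0000
377.27933 36.2400
107.08579 9.6800
271.12012 5.3300
359.26834 5.1700
END IONS

BEGIN IONS
TITLE=M10_neg
PEPMASS=371.13492
CHARGE=1-
147.11789 100.0000
371.17041 67.3500
209.11717 4.6900
179.05547 2.8300
191.10738 2.6800
149.04442 2.1600
293.94162 1.7800
207.10025 1.7300
END IONS

BEGIN IONS
TITLE=M11_pos
PEPMASS=395.13120
CHARGE=1+
395.20325 100.0000
203.05223 23.0200
201.03685 6.2600
217.15601 5.5200
215.14053 4.3900
121.10120 1.8000
END IONS

BEGIN IONS
TITLE=M12_pos
PEPMASS=241.10716
CHARGE=1+
241.16249 100.0000
123.11669 25.3100
147.11676 13.5800
END IONS

BEGIN IONS
TITLE=M13_pos
PEPMASS=251.08891
CHARGE=1+
98.98458 100.0000
251.08862 76.5300
251.12540 61.8900
141.09071 7.5100
167.08630 6.8100
173.13144 5.0600
END IONS

BEGIN IONS
TITLE=M13_neg
PEPMASS=227.09253
CHARGE=1-
227.12891 100.0000
183.13898 30.8100
165.12851 27.8000
209.11829 25.1900
END IONS

BEGIN IONS
TITLE=M14_neg
PEPMASS=371.13239
CHARGE=1-
371.11700 100.0000
291.16016 66.4600
79.95737 30.9300
247.17033 30.1400
371.24493 24.6600
122.03730 17.2600
123.04517 13.9800
135.04510 13.0600
END IONS

BEGIN IONS
TITLE=M15_neg
PEPMASS=223.09724
CHARGE=1-
223.11705 100.0000
122.10566 13.9800
179.12711 44.8500
END IONS

BEGIN IONS
TITLE=M16_pos
PEPMASS=727.28077
CHARGE=1+
409.09137 100.0000
427.10205 98.0400
391.08096 72.5500
379.08099 71.1100
511.12332 50.9800
481.11246 50.1200
325.07050 40.0000
349.07037 33.5700
337.07034 24.3500
355.08121 23.5000
END IONS

BEGIN IONS
TITLE=M16_neg
PEPMASS=725.26600
CHARGE=1-
353.06680 100.0000
443.09808 76.6500
473.10849 34.9900
725.19037 33.4800
545.12988 18.6200
413.08752 15.0600
407.07764 11.0600
END IONS

BEGIN IONS
TITLE=M17_pos
PEPMASS=729.29643
CHARGE=1+
127.03926 100.0000
189.08713 53.8900
156.07675 41.8100
155.08171 19.5500
213.09970 16.2100
159.07664 15.3600
END IONS

BEGIN IONS
TITLE=M17_neg
PEPMASS=727.28078
CHARGE=1-
212.00232 100.0000
217.01762 43.2300
80.96514 21.3500
261.00748 17.7300
213.00554 10.5500
137.06081 10.2700
END IONS

BEGIN IONS
TITLE=M18_pos
PEPMASS=227.12790
CHARGE=1+
227.06352 100.0000
209.11656 71.1400
END IONS

BEGIN IONS
TITLE=M19_neg
PEPMASS=663.17542
CHARGE=1-
112.98559 100.0000
323.22034 32.7000
255.23296 25.1600
391.20743 10.0300
END IONS

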