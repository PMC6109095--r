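# Nav1.5 (SCN5A isoform 1, 2016 aa) region model derived from NCBI/UniProt
# transmembrane annotations. Boundaries are editable: downstream code reads
# only this table, so alternative annotations can be dropped in.
# kind: terminus | segment | segment-linker | domain-linker
# side: cytoplasmic | transmembrane | extracellular
name	kind	domain	segment	start	end	side
N	terminus	0	0	1	126	cytoplasmic
D1S1	segment	1	1	127	145	transmembrane
D1L12	segment-linker	1	0	146	155	extracellular
D1S2	segment	1	2	156	175	transmembrane
D1L23	segment-linker	1	0	176	185	cytoplasmic
D1S3	segment	1	3	186	203	transmembrane
D1L34	segment-linker	1	0	204	209	extracellular
D1S4	segment	1	4	210	229	transmembrane
D1L45	segment-linker	1	0	230	245	cytoplasmic
D1S5	segment	1	5	246	265	transmembrane
D1L56	segment-linker	1	0	266	371	extracellular
D1S6	segment	1	6	372	396	transmembrane
L12	domain-linker	0	0	397	711	cytoplasmic
D2S1	segment	2	1	712	731	transmembrane
D2L12	segment-linker	2	0	732	738	extracellular
D2S2	segment	2	2	739	758	transmembrane
D2L23	segment-linker	2	0	759	771	cytoplasmic
D2S3	segment	2	3	772	790	transmembrane
D2L34	segment-linker	2	0	791	804	extracellular
D2S4	segment	2	4	805	823	transmembrane
D2L45	segment-linker	2	0	824	840	cytoplasmic
D2S5	segment	2	5	841	860	transmembrane
D2L56	segment-linker	2	0	861	914	extracellular
D2S6	segment	2	6	915	939	transmembrane
L23	domain-linker	0	0	940	1201	cytoplasmic
D3S1	segment	3	1	1202	1220	transmembrane
D3L12	segment-linker	3	0	1221	1232	extracellular
D3S2	segment	3	2	1233	1252	transmembrane
D3L23	segment-linker	3	0	1253	1266	cytoplasmic
D3S3	segment	3	3	1267	1286	transmembrane
D3L34	segment-linker	3	0	1287	1298	extracellular
D3S4	segment	3	4	1299	1317	transmembrane
D3L45	segment-linker	3	0	1318	1336	cytoplasmic
D3S5	segment	3	5	1337	1356	transmembrane
D3L56	segment-linker	3	0	1357	1446	extracellular
D3S6	segment	3	6	1447	1471	transmembrane
L34	domain-linker	0	0	1472	1523	cytoplasmic
D4S1	segment	4	1	1524	1542	transmembrane
D4L12	segment-linker	4	0	1543	1554	extracellular
D4S2	segment	4	2	1555	1574	transmembrane
D4L23	segment-linker	4	0	1575	1586	cytoplasmic
D4S3	segment	4	3	1587	1606	transmembrane
D4L34	segment-linker	4	0	1607	1622	extracellular
D4S4	segment	4	4	1623	1641	transmembrane
D4L45	segment-linker	4	0	1642	1658	cytoplasmic
D4S5	segment	4	5	1659	1678	transmembrane
D4L56	segment-linker	4	0	1679	1748	extracellular
D4S6	segment	4	6	1749	1772	transmembrane
C	terminus	0	0	1773	2016	cytoplasmic
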