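# Synthetic 59-locus HCC focus panel (editable).
# Cytoband names mirror loci recurrently amplified or deleted in hepatocellular
# carcinoma, but this file is a constructed stand-in assembled for
# demonstration and testing: prevalences and the exact locus list are NOT
# taken from any single published supplementary table.
# Columns: locus (cytoband), direction (gain/loss), tag (free-text citation tag).
locus	direction	tag
1p36.32	loss	hcc-panel
1q21.3	gain	hcc-panel
1q22	gain	hcc-panel
1q32.1	gain	hcc-panel
1q42.3	gain	hcc-panel
2q33.2	loss	hcc-panel
3p21.31	loss	hcc-panel
4p14	loss	hcc-panel
4q13.3	loss	hcc-panel
4q21.23	loss	hcc-panel
4q22.1	loss	hcc-panel
4q34.3	loss	hcc-panel
4q35.2	loss	hcc-panel
5p15.33	gain	hcc-panel
5q13.2	loss	hcc-panel
6p21.1	gain	hcc-panel
6q14.1	loss	hcc-panel
6q27	loss	hcc-panel
7q31.2	gain	hcc-panel
8p21.3	loss	hcc-panel
8p22	loss	hcc-panel
8p23.1	loss	hcc-panel
8q11.23	gain	hcc-panel
8q21.13	gain	hcc-panel
8q24.21	gain	hcc-panel
8q24.3	gain	hcc-panel
9p21.3	loss	hcc-panel
10q23.31	loss	hcc-panel
11p15.5	gain	hcc-panel
11q13.3	gain	hcc-panel
12q14.1	gain	hcc-panel
13q14.2	loss	hcc-panel
13q34	gain	hcc-panel
14q32.33	loss	hcc-panel
16p13.3	loss	hcc-panel
16q23.1	loss	hcc-panel
17p13.1	loss	hcc-panel
17q25.3	gain	hcc-panel
19p12	loss	hcc-panel
19q13.42	gain	hcc-panel
20p11.21	gain	hcc-panel
20q11.21	gain	hcc-panel
20q13.12	gain	hcc-panel
20q13.33	gain	hcc-panel
21q22.3	loss	hcc-panel
22q13.31	loss	hcc-panel
1p13.3	loss	hcc-panel
2p24.3	gain	hcc-panel
3q26.2	gain	hcc-panel
5q21.3	loss	hcc-panel
6p21.33	gain	hcc-panel
7p11.2	gain	hcc-panel
9q34.11	loss	hcc-panel
10p15.1	gain	hcc-panel
11q22.2	gain	hcc-panel
13q12.11	gain	hcc-panel
15q26.3	loss	hcc-panel
18q21.2	loss	hcc-panel
Xq28	gain	hcc-panel
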