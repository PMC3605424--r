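rank	protein	degree	coewc	essentiality
104	YDR365C	23	1.698583	essential
124	YDL232W	18	1.503577	essential
127	YJL033W	19	1.49437	essential
128	YGL099W	14	1.492625	essential
130	YBR234C	23	1.473234	essential
131	YIL075C	32	1.472131	essential
139	YLR200W	10	1.435959	non-essential
145	YDL087C	23	1.401966	essential
147	YKL095W	38	1.390057	essential
151	YHR081W	5	1.358778	non-essential
152	YPR088C	14	1.351337	essential
154	YOL094C	37	1.327599	essential
156	YHL030W	21	1.310346	non-essential
158	YOR259C	28	1.282556	essential
161	YBL041W	9	1.275247	essential
163	YNL182C	21	1.268987	essential
170	YMR314W	16	1.246819	essential
178	YBR126C	29	1.219773	non-essential
179	YOL142W	6	1.219508	essential
181	YBL023C	14	1.211368	essential
187	YNL290W	34	1.176549	essential
190	YFL008W	24	1.156859	essential
191	YPL012W	20	1.153688	essential
193	YER025W	26	1.140787	essential
194	YOR210W	16	1.138906	essential
199	YKL068W	35	1.119936	non-essential
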