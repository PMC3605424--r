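protein	pcc	cc	essentiality
YDR280W	0.8046	0.3399	essential
YER025W	0.639	0.1354	essential
YNL265C	-0.357	0.1648	non-essential
YGR195W	0.771	0.4083	essential
YGR095C	0.7414	0.3897	essential
YOL021C	0.8391	0.375	essential
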