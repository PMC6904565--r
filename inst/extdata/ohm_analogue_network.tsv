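kind	vessel	element	node_a	node_b	resistance
lumen	top_left	upstream	U	a2	0.25
lumen	top_left	downstream	a2	a3	0.25
lumen	bottom_left	upstream	U	b2	0.25
lumen	bottom_left	downstream	b2	b3	0.25
lumen	central	upstream	c1	c2	0.25
lumen	central	downstream	c2	c3	0.25
lumen	top_right	upstream	d1	d2	0.25
lumen	top_right	downstream	d2	D	0.25
lumen	bottom_right	upstream	e1	e2	0.25
lumen	bottom_right	downstream	e2	D	0.25
wall	NA	NA	a2	c1	1
wall	NA	NA	a3	c1	1
wall	NA	NA	c2	e2	1
wall	NA	NA	a3	d1	1
wall	NA	NA	b3	e1	1
wall	NA	NA	a2	b2	1
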