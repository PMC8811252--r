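guide_id	group	chopchop	ssc	crisprater	in_vivo
gJ	GWD-5p	1	1	1	1
gK	GWD-5p	3	4	3	4
gL	GWD-5p	4	3	2	2
gM	GWD-5p	2	2	2	3
gA	GWD-3p	2	5	1	5
gB	GWD-3p	3	4	5	6
gC	GWD-3p	5	2	4	1
gD	GWD-3p	4	3	2	2
gE	GWD-3p	6	6	3	4
gI	GWD-3p	1	1	6	3
g43	DMR6-5p	2	1	1	1
g44	DMR6-5p	1	2	2	3
g45	DMR6-5p	3	3	3	2
g46	DMR6-3p	2	2	1	2
g47	DMR6-3p	3	1	2	1
g48	DMR6-3p	1	3	3	3
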