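position	parent	retro
-135	T	T/C
47	C	C/A
126	T	T/C
144	G	A
165	T/C	T
190	G	G/T
246	T/G	T
276	G/A	G
363	C/T	C
531	C/T	C
552	A	A/T
629	C	C/T
754	A	A/C
759	G	C
798	C/T	C
916	T	T/del
*7	G	G/A
*44	G	G/A
*184	repeat:12/repeat:17	repeat:12/repeat:17
*223	repeat:17/repeat:20	repeat:17/repeat:20
*243	G/A	G
*310	T/C	T
*313	C	C/G
*315	C	C/T
*413	G/A	G
*467	G	G/A
*496	T/del	T
*512	G	G/A
*552	T/del	del
*606	T	G
*663	A/G	A
*802	C/T	C
*843	C/T	C
*875	G/A	A
*910	C/A	C
*956	A/G	A
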