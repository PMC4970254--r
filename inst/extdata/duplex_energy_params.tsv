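type	key1	key2	value
stack	AU	AU	-0.93
stack	AU	UA	-1.1
stack	AU	CG	-2.24
stack	AU	GC	-2.08
stack	AU	GU	-0.9
stack	AU	UG	-1
stack	UA	AU	-1.33
stack	UA	UA	-0.93
stack	UA	CG	-2.35
stack	UA	GC	-2.11
stack	UA	GU	-1.03
stack	UA	UG	-0.98
stack	CG	AU	-2.11
stack	CG	UA	-2.08
stack	CG	CG	-3.26
stack	CG	GC	-2.36
stack	CG	GU	-1.34
stack	CG	UG	-1.6
stack	GC	AU	-2.35
stack	GC	UA	-2.24
stack	GC	CG	-3.42
stack	GC	GC	-3.26
stack	GC	GU	-1.68
stack	GC	UG	-1.7
stack	GU	AU	-0.98
stack	GU	UA	-1
stack	GU	CG	-1.7
stack	GU	GC	-1.6
stack	GU	GU	-0.78
stack	GU	UG	-0.81
stack	UG	AU	-1.03
stack	UG	UA	-0.9
stack	UG	CG	-1.68
stack	UG	GC	-1.34
stack	UG	GU	-0.71
stack	UG	UG	-0.78
loop	0	1	3.8
loop	0	2	2.8
loop	0	3	3.2
loop	0	4	3.6
loop	1	0	3.8
loop	1	1	1.5
loop	1	2	1.8
loop	1	3	2
loop	1	4	2.2
loop	2	0	2.8
loop	2	1	1.8
loop	2	2	2
loop	2	3	2.2
loop	2	4	2.5
loop	3	0	3.2
loop	3	1	2
loop	3	2	2.2
loop	3	3	2.5
loop	3	4	2.8
loop	4	0	3.6
loop	4	1	2.2
loop	4	2	2.5
loop	4	3	2.8
loop	4	4	3
scalar	duplex_init	NA	4.09
scalar	au_end_penalty	NA	0.45
scalar	max_loop_per_side	NA	4
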