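pattern	replacement	scope
mc	mac	initial
x	z	initial
ps	s	initial
pt	t	initial
ts	s	initial
ae	e	any
oe	e	any
ph	f	any
th	t	any
sz	s	any
ch	c	noninitial
y	i	any
k	c	any
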