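set_label	orthography	phonemes	pp
PP_plus	dini	d͡ʒ i n i	0.0090
PP_plus	deta	d e t a	0.0085
PP_plus	pemi	p e m i	0.0082
PP_plus	sute	s u t e	0.0084
PP_plus	viko	v i k o	0.0080
PP_plus	bara	b a r a	0.0090
PP_minus	nipe	n i p e	0.0066
PP_minus	tadi	t a d͡ʒ i	0.0074
PP_minus	mide	m i d e	0.0075
PP_minus	teba	t e b a	0.0074
PP_minus	kosu	k o s u	0.0078
PP_minus	ravi	r a v i	0.0073
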