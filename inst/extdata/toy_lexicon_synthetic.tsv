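# synthetic Brazilian-Portuguese-flavoured frequency lexicon (toy, invented
# orthographies/frequencies for demonstration and testing only)
bala	b a l a	1200
bola	b o l a	5200
bata	b a t a	800
barata	b a r a t a	900
cabana	k a b a n a	180
capela	k a p e l a	280
cama	k a m a	1600
capa	k a p a	400
casa	k a z a	8800
cebola	s e b o l a	700
copo	k o p o	1300
costa	k o s t a	2200
dama	d a m a	350
data	d a t a	1100
dedo	d e d o	2100
dia	d͡ʒ i a	9500
dita	d͡ʒ i t a	300
duna	d u n a	150
fadiga	f a d͡ʒ i g a	200
fila	f i l a	700
fita	f i t a	450
gato	g a t o	1900
gota	g o t a	350
quilo	k i l o	600
lata	l a t a	500
lado	l a d o	3200
mala	m a l a	650
mapa	m a p a	900
medo	m e d o	2600
menino	m e n i n o	2800
mesa	m e z a	2400
mina	m i n a	550
mito	m i t o	480
nada	n a d a	4100
nivel	n i v e l	900
nome	n o m e	5100
nota	n o t a	1500
pato	p a t o	700
pele	p e l e	1200
pena	p e n a	800
peso	p e z o	1400
pipa	p i p a	250
rato	r a t o	900
rede	r e d e	1100
sala	s a l a	2900
sede	s e d e	950
sino	s i n o	320
sopa	s o p a	850
suco	s u k o	1000
tarde	t a r d͡ʒ i	3900
tatu	t a t u	300
tela	t e l a	1700
teto	t e t o	600
tinta	t͡ʃ i n t a	750
tipo	t͡ʃ i p o	5600
vaca	v a k a	800
vida	v i d a	6200
vila	v i l a	550
zona	z o n a	400
la	l a	1
ave	a v e	120
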