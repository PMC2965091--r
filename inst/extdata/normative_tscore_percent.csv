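class,percent
<50,50.00
50-64,43.32
65-74,6.06
>=75,0.62
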