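R	group	delta
5	1	5.44e-5
5	2	2.72e-4
5	3	1.36e-3
5	4	6.8e-3
2	1	2e-4
2	2	4e-4
2	3	8e-4
2	4	1.6e-3
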