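# Degenerate primer sets targeting the iron-nitrogenase gene anfD, as
# produced by a reference-guided web design tool (five pairs). Used as a
# test-mode evaluation fixture.
set	orientation	sequence
1	forward	WGCACGCCGTGRTSAAGGGC
1	reverse	TGCCAGGTGTCGTAGGTGCAGCCS
2	forward	WGCACGCCGTGRTSAAGGGC
2	reverse	GCCAGGTGTCGTAGGTGCAGCCS
3	forward	WGCACGCCGTGRTSAAGGGC
3	reverse	CCAGGTGTCGTAGGTGCAGCCS
4	forward	WGCACGCCGTGRTSAAGGGC
4	reverse	CAGGTGTCGTAGGTGCAGCCS
5	forward	WGCACGCCGTGRTSAAGGGC
5	reverse	AGGTGTCGTAGGTGCAGCCS
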