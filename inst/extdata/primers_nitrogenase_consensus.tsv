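# Concrete primer sets for the nitrogenase genes anfD, nifK and vnfD, as
# produced by a consensus-plus-Primer3 pipeline (five pairs per gene; odd
# rows forward, even rows reverse). Used as a test-mode evaluation fixture.
gene	num	orientation	sequence
anfD	1	forward	CTTCCAGCTGAAGTACACC
anfD	2	reverse	CACCACAAGATCAACATCG
anfD	3	forward	TTCCAGCTGAAGTACACC
anfD	4	reverse	CACCACAAGATCAACATCG
anfD	5	forward	CTTCCAGCTGAAGTACACC
anfD	6	reverse	CCACCACAAGATCAACATC
anfD	7	forward	TTCCAGCTGAAGTACACC
anfD	8	reverse	CCACCACAAGATCAACATC
anfD	9	forward	TTCCAGCTGAAGTACACCT
anfD	10	reverse	CACCACAAGATCAACATCG
nifK	1	forward	TGAAGACCAGCATCAAGAA
nifK	2	reverse	AACAACAAGGTGAACCTGAT
nifK	3	forward	TGAAGACCAGCATCAAGAA
nifK	4	reverse	ACAACAAGGTGAACCTGAT
nifK	5	forward	TGAAGACCAGCATCAAGAA
nifK	6	reverse	CTTCAGCAACATGGTGAAG
nifK	7	forward	GAAGACCAGCATCAAGAAC
nifK	8	reverse	AACAACAAGGTGAACCTGAT
nifK	9	forward	CTGAAGACCAGCATCAAGAA
nifK	10	reverse	AACAACAAGGTGAACCTGAT
vnfD	1	forward	GGACTTCGAGAAGGTGATC
vnfD	2	reverse	GTACATGGGCTTCGAGG
vnfD	3	forward	AGGACTTCGAGAAGGTGAT
vnfD	4	reverse	GTACATGGGCTTCGAGG
vnfD	5	forward	GAGGACTTCGAGAAGGTG
vnfD	6	reverse	GTACATGGGCTTCGAGG
vnfD	7	forward	GACTTCGAGAAGGTGATCG
vnfD	8	reverse	GTACATGGGCTTCGAGG
vnfD	9	forward	AACGAGCTGGAGTTCTTC
vnfD	10	reverse	GTACATGGGCTTCGAGG
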