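# Published per-family BLAST-hit counts for genes implicated in bacterial
# cold-shock response, for P. priestleyi BC1401 and three relatives with
# complete genomes. Used for census aggregation and comparison reporting.
family	BC1401	PCC6306	JSC12	PCC7407
aceE	1	2	2	1
aceF	1	2	1	1
csp-family	1	1	0	1
deaD	1	1	1	1
desAB	2	2	1	2
dnaA	1	1	1	1
gyrA	2	2	2	2
dnaK	5	5	6	4
dnaJ	1	1	1	1
hupB	4	3	3	1
infA/IF-1	1	1	1	1
infB/IF-2	1	1	1	1
infC/IF-3	1	1	2	2
nusA	1	1	1	1
otsA	0	0	0	1
pnp	1	1	1	1
rnr	1	1	1	1
rbfA	1	1	1	1
recA	1	1	1	1
tig	1	1	1	1
yfiA	1	0	1	1
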