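chrom	length_bp
1	50958780
2	50875105
3	39785425
4	36856235
5	36662141
6	30271285
7	30232436
8	25778047
9	23273890
10	22735115
11	21046404
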