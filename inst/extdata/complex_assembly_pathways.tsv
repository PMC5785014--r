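# Literature-curated assembly orders for 21 multimeric complexes (3-7
# chains) with experimental or inferred evidence of assembly order.
# Columns: PDB id, number of chains, assembly pathway(s) in the package's
# text notation (primes mark chains with identical sequence; alternatives
# joined by " or ").
id	n_chains	pathway
1a0r	3	BG> BGP
1ikn	3	AC> ACD
1vcb	3	AB> ABC
2aze	3	AB> ABC
1es7	4	AA'> AA'B> AA'BB'
1gpq	4	AA'> AA'C> AA'CC'
2e9x	4	BD> ABD> ABCD
1kf6	4	CD> BCD> ABCD
2bq1	4	EE'+II'> EE'II'
2qsp	4	AB> AB+A'B'> AA'BB'
3fh6	4	AA'> AA'F or AA'> AA'G or AA'+FG> AA'FG
1hez	5	AB> AB+A'B'> AB+A'B'E> AA'BB'E
1w88	5	AA'BB'> AA'BB'I
1du3	6	DD'> DD'D''> ADD'D''> AA'DD'D''> AA'A''DD'D''
1rlb	6	AA'> AA'+A''A'''> AA'A''A'''> AA'A''A'''E> AA'A''A'''EE'
1s5b	6	B1B2> B1B2B3> AB1B2B3> AB1B2B3B4> AB1B2B3B4B5
3vyt	6	CD+C'D'+EE'> CD+C'D'EE'> CC'DD'EE'
4hi0	6	FH+F'H'+GG'> FF'HH'+GG'> FF'GG'HH'
4igc	6	AA'> AA'C> AA'C+DE> AA'CDE> AA'CDEX
3uku	7	CG+DF> ACDFG> ABCDEFG
4gwp	7	ABD> ABCDG+EF> ABCDEFG
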