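>MBP-1 source=published_candidate_table
SPAGGQDF
>MBP-2 source=published_candidate_table
WGTNGGTR
>MBP-3 source=published_candidate_table
APRGGNTS
>MBP-4 source=published_candidate_table
PQYPPHDN
>MBP-5 source=published_candidate_table
GLPKPGGN
>MBP-6 source=published_candidate_table
PQKGGMWD
>MBP-7 source=published_candidate_table
WSPNFWWR
>MBP-8 source=published_candidate_table
WHPRPVWE
>MBP-9 source=published_candidate_table
YHFPYFRF
>MBP-10 source=published_candidate_table
YGDGYFRF
>MBP-11 source=published_candidate_table
YHDGYFRF
>poliALA source=published_candidate_table
AAAAAAAA
>NEG source=published_candidate_table
AAARRAAA
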