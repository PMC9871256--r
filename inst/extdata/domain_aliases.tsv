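# Normalization of HMM/CDD model names to canonical NLR part labels.
# pattern is a case-insensitive regular expression matched against the raw
# model name; the first matching row wins; unmatched names become OTHER.
pattern	label
^NB-ARC$	NBS
^NBS$	NBS
^PF00931	NBS
^NB_ARC	NBS
^TIR(_[0-9]+)?$	TIR
^PF01582	TIR
^RX-CC_like$	CC
^CC$	CC
^Rx_N$	CC
^coiled-coil$	CC
^RPW8$	RPW8
^PF05659	RPW8
^LRR(_[0-9]+)?$	LRR
^PF0056[05]	LRR
^PF07725	LRR
^PF12799	LRR
^PF13306	LRR
^PF13855	LRR
^LRR_RI$	LRR
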