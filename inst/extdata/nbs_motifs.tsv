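# Curated consensus library for the conserved NB-ARC (NBS) motifs of plant
# NLR proteins, in N-to-C order along the domain.  Consensus strings follow
# the motif descriptions of the classical Arabidopsis/legume NBS-LRR
# surveys; lower-information positions are wildcards ('x').  `required`
# marks the six motifs counted in presence summaries; RNBS-A and RNBS-B are
# scanned but optional.  `threshold` is the presence cutoff as a fraction of
# the maximum attainable PSSM score.
name	consensus	required	threshold
P-loop	GxGGxGKTT	1	0.6
RNBS-A	FDxxAWxxVS	0	0.6
kinase-2	LLVLDDVW	1	0.6
RNBS-B	GSxIIxTTRD	0	0.6
RNBS-C	LSxDEAWxLF	1	0.6
GLPL	GLPLAL	1	0.6
RNBS-D	CFLYCxLFPED	1	0.6
MHDV	MHDLxREMA	1	0.6
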