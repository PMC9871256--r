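---
title: "Methods: genome-wide NLR family analysis with nlratlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide NLR family analysis with nlratlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlratlas)
```

# The analysis and its assumptions

NLR (NBS-LRR) proteins are plant intracellular immune receptors built from
up to three parts: an N-terminal signalling domain (coiled-coil CC,
Toll/interleukin-1-receptor TIR, or RPW8), the central NB-ARC (NBS)
nucleotide-binding domain, and C-terminal leucine-rich repeats (LRR).
`nlratlas` turns the *evidence tables* of a genome-wide survey — domain
scans, homology searches, expression matrices — into a complete family
profile. Running the searches themselves (hmmsearch, BLASTp, CDD,
alignment programs) is deliberately out of scope: the package consumes
their standard tabular outputs, which keeps every stage deterministic and
testable.

## Identification and classification

A gene is a candidate when its best NB-ARC HMM hit has E-value at or below
`e_nbs = 1e-4` (inclusive; the classical cutoff for the NB-ARC profile).
Candidates without a hit against a reference NLR protein set at
`e_screen = 1e-5` are eliminated. The reference screen threshold is a
package choice — surveys typically state the elimination step without a
cutoff — and both values are arguments of `classify_nlr()`.

Subclass assignment uses the domain-scan evidence first, with priority
RPW8 → RNL, then TIR → TNL, then CC → CNL. The priority order resolves the
(rare) case of several N-terminal domain types on one protein in favour of
the rarer, more specific signals; such calls are flagged `multi_nterm`.
When no N-terminal domain was detected at all (architecture codes `N` and
`NL`), the subclass of the best reference homolog is used — domain
evidence always beats the homology fallback when both exist. With neither,
the call defaults to CNL and is flagged `low_confidence`.

The architecture code concatenates the present parts in N-to-C order
(leading `C`/`T`/`R` only when that domain was actually detected, always
`N`, trailing `L` for LRR), so `CNL`, `TNL`, `RNL` are the *typical*
three-part architectures and `CN`, `TN`, `NL`, `N` the atypical ones.
Integrated (non-canonical) domains such as PLN03210 are retained when the
hit is confident (E < 1e-5, strict) *and* covers at least 90% of the
domain model; "complete domain" is interpreted as this coverage fraction
because E-values alone do not distinguish fragments, and the fraction is
configurable. Aliases are `Mru<chr>c<serial>` with the serial being the
gene's genome-wide rank by (chromosome in natural order, start, gene id) —
the tie-break by gene id makes alias assignment order-independent.

## Motif presence

The conserved NB-ARC motifs are called by sliding a consensus-derived
position-specific score matrix over the protein (restricted to the NBS hit
interval ± 30 residues when domain coordinates are available). Consensus
positions score +2 for a match and −1 otherwise; wildcard positions score
+1 uniformly, so substitutions there never change the score. A motif is
present when the best window reaches `threshold = 0.6` of the maximum
attainable score: an exact consensus saturates, one or two substitutions
in an 8–11 residue motif still pass, three or more fail. The shipped
library (`inst/extdata/nbs_motifs.tsv`) lists P-loop, RNBS-A, kinase-2,
RNBS-B, RNBS-C, GLPL, RNBS-D and MHDV in canonical N-to-C order; the six
summary-counted motifs are P-loop, kinase-2, RNBS-C, GLPL, RNBS-D and
MHDV, while RNBS-A/B are scanned but optional (their consensus differs
strongly between TIR and non-TIR proteins, and they are the motifs most
often absent from RNL). The library is a plain TSV and fully replaceable;
de-novo motif discovery is a non-goal.

## Clusters and chromosomal distribution

Physical clusters use single-linkage chaining along each chromosome:
consecutive family genes join one cluster when the *intergenic* gap
`max(0, next_start − prev_end)` is strictly below `max_gap = 250000` bp.
The end-to-start (intergenic) convention was chosen over start-to-start or
midpoint distance because it is the only one that is invariant to gene
length; the rule is strict, so two genes exactly 250 kb apart remain
separate. The 250-kb window / 1-kb step sliding density track
(`sliding_density()`) is for plotting and export only; clustering uses the
chaining rule, not the window.

## Duplication types and synteny

Collinearity follows the MCScanX recipe in rank space. Homology hits are
cleaned (`build_homology_graph()`: self-hits removed, top 5 subjects per
query at E ≤ 1e-5, reciprocal pairs collapsed), every gene receives a
positional rank on its chromosome, and each homolog pair becomes an anchor
`(rank_a, rank_b)`. Chains extend between anchors when both rank gaps are
positive, at most `max_rank_gap = 25`, and the second axis is monotone
(increasing or decreasing — the block's orientation); each anchor adds
`match_score = 50` and each link pays `gap_penalty × (Δrank_a + |Δrank_b| − 2)`
with `gap_penalty = −1`. These are the MCScanX defaults, used because the
method is named in the field without parameters. The dynamic program keeps
the chain length in its state — `v[j, l]` is the best score of an
`l`-anchor chain ending at anchor `j` — because maximising score alone can
discard a lower-scoring chain that is the only one reaching the
`min_anchors = 5` block threshold; with the length in the state the
extraction is exactly the constrained optimum, which the test suite checks
against exhaustive search over all monotone anchor subsets. Blocks are
extracted greedily by descending chain score, removing the anchors of each
accepted block, so every anchor belongs to at most one block.

Duplicate labels are assigned by strict priority: **segmental** (gene is a
block anchor), **tandem** (homolog at adjacent rank on the same
chromosome), **proximal** (homolog within 10 ranks), **dispersed** (any
other homolog), otherwise no-homolog singleton. Ranks default to the whole
annotation (`rank_space = "all"`), the MCScanX semantics; a family-only
rank space (`rank_space = "nlr"`) is available because some published
analyses feed only family sequences to the homology search, which
implicitly ranks within the family. Cross-species synteny is the same
chaining with ranks computed within each species independently.

## Phylogeny

Protein distances use the Poisson correction `d = −ln(1 − p)` on the
proportion of differing sites (the usual default for protein
neighbor-joining), with plain p-distance available; gap columns are
removed pairwise (complete deletion by flag). Saturated pairs (`p ≥ 1`)
are an error under the Poisson model rather than silently capped.

`nj_tree()` implements Saitou–Nei agglomeration with the standard
Q-criterion. Two numerical choices matter: ties in Q are broken by the
lexicographically smallest pair of representative taxon labels, making the
topology independent of input row order; and negative branch-length
estimates (which NJ can produce on non-additive data) are clamped to zero
with the count recorded in the `"negative_clamped"` attribute. On additive
matrices the method is exact: the tests verify that random additive trees
(up to 12 taxa) are reproduced to 1e-9 in the path metric and that the
5-taxon topology equals an exhaustive least-squares search over all 15
topologies.

Bootstrap supports resample alignment columns with replacement (default
500 replicates, explicit seed required and stored in the output); the
support of a bipartition is the percentage of replicate NJ trees
containing it. Replicates whose resample saturates the Poisson distance
are skipped and counted.

The pipeline builds its typical-gene tree from the NBS (NB-ARC) region cut
at the domain-hit coordinates. This follows the common family-tree
practice of comparing the conserved domain; it requires equal-length
regions and errors otherwise, in which case a pre-aligned FASTA can be
supplied directly via `aligned_block()`. A bundled progressive aligner was
considered and omitted: alignment quality would dominate the result while
pretending to reproduce external aligners, and pre-aligned input is the
honest interface.

## Expression screen

A gene is *expressed* when FPKM exceeds 0 in at least one sample — surveys
rarely define this threshold, so it is exposed (`min_fpkm`,
`min_samples`). The fold change between the resistant and susceptible
group means uses a pseudocount of 0.01 so zero denominators stay finite,
and the `min_fold = 1.5` flag is boundary-inclusive. Genes with one group
mean exactly zero and the other positive are additionally reported as
absent in that variety. Group means are taken over the biological
replicates (three per variety in the reference design). No
differential-expression statistics are computed — the screen is a fold
filter, matching the analysis it implements, and `heatmap_export()`
produces the log2(FPKM+1) or row-z-score matrix for plotting.

# The synthetic-genome generator

`simulate_genome()` is first-class, tested code that defines the package's
reference study conditions: eight chromosomes, 440 background genes and 60
planted NLRs (~500 genes total). The default plan
(`default_nlr_plan()`) plants, by construction rather than by running the
pipeline: 35 CNL / 21 TNL / 4 RNL with a realistic mix of typical and
atypical codes; 15 physical clusters of sizes 2–7 (40 clustered genes, 20
singletons, all inter-cluster gaps ≥ 300 kb and intra-cluster gaps well
below 250 kb); 16 tandem, 8 proximal, 10 dispersed and 12 segmental
duplicates (two order-preserving runs of six genes copied across
chromosomes) plus 14 genes without homologs; planted motif corruptions
including one zero-of-six protein; integrated domains on four genes; and
expression classes (2.5-fold induction, absent-in-susceptible, silent,
flat) with multiplicative log-normal noise of sd 0.1 on three replicates
per group.

NLR proteins are concatenations of fixed domain blocks; the NBS block
assembles the motif-library consensus in canonical order with 12-residue
linkers whose every third position carries a subclass-specific residue, so
the three subclasses diverge cleanly and form three clades. Per-gene
variation (rate 0.05, copies +0.03) touches only linker positions, keeping
motif and domain evidence exact unless a corruption is planted. Background
amino acids are uniform over the 20 residues — simplicity over realism;
the signal lives in the blocks. The homology table is fabricated from the
known copy relationships rather than by running an aligner, with three
planted decoys exercising the identification filters (NBS hits at 2e-4 and
3e-4 that fail the E-value cutoff, and one at 5e-5 with no reference
support). A `spurious_hit_rate` knob adds random homology rows (as a
fraction of the true rows) to probe the duplicate classifier's
degradation.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: intron structure and real gene length
distributions, nucleotide-level evolution (duplicates diverge by linker
substitution only), domain-scan noise (coordinates and E-values are clean
apart from the planted decoys), partially overlapping or nested clusters,
and the long-tailed homology networks of real families. Recovery rates of
100% on noiseless synthetic data validate the *logic* of each stage, not
its robustness to annotation error.

Everything derives deterministically from the mandatory seed: identical
configurations produce byte-identical files (`write_simulation()`).

# Problem sizes and runtime choices

The test suite and the acceptance script run end-to-end analyses on the
reference ~500-gene genome (seconds per run), exhaustive chain-search
oracles on 200 random instances of up to 12 anchors, least-squares
topology oracles on 100 random 5-taxon instances, NJ consistency checks up
to 12 taxa, and a 500-replicate bootstrap on the ~35 typical planted
genes. These sizes make every oracle fully exhaustive while keeping the
whole suite under a minute of compute; the pipeline itself scales to real
genome annotations (tens of thousands of genes) since all per-stage costs
are dominated by the homology table and the anchor counts per chromosome
pair, not by genome length.

# Known limitations

- The homology fallback for subclass assignment trusts `CNL`/`TNL`/`RNL`
  tokens in reference subject names; a reference set without such naming
  needs a custom fallback mapping.
- The NBS-region tree requires equal-length domain cuts; heterogeneous
  domain spans require externally aligned input.
- Duplicate labels depend on the chosen rank space; family-only ranks make
  "tandem" mean "adjacent family member", not "adjacent gene".
- Pseudogene detection, Ka/Ks dating, de-novo motif discovery and all
  rendering (ideograms, Circos, tree figures) are non-goals; the package
  exports the standard text formats those tools consume.
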