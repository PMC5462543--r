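---
title: "Methods: reconstructing an ancestral plastid proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing an ancestral plastid proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoplastid)
```

## The problem

Secondary plastids, such as those of the ochrophyte algae, are serviced by
hundreds of nucleus-encoded proteins that are imported across multiple
membranes. Reconstructing which of these proteins were already
plastid-targeted in the last common ochrophyte ancestor — and which donor
lineage each derives from — requires a chain of comparative analyses:
orthologous group assembly, taxonomic conservation calibration, alignment
curation, dual (similarity- and tree-based) origin assignment, residue-level
synapomorphy analysis, chimeric-protein detection, and enrichment
statistics. `paleoplastid` implements that chain as composable functions
plus an orchestrating `run_pipeline()`, and validates it on a seeded
synthetic dataset with planted ground truth.

## Taxonomy

Sequences are binned into sub-categories, each mapped to a lineage
(`default_taxonomy()`). The eleven ochrophyte sub-categories form three
groups — chrysista (3), hypogyristea (3) and diatoms (5). Candidate donor
lineages (red algae, green algae, aplastidic stramenopiles, prokaryotes,
other eukaryotes, viruses) constitute the outgroup search space; CASH
lineages (cryptomonads, haptophytes, dinotoms, other alveolates, plus
euglenids and chlorarachniophytes) are excluded from outgroup searches
because their histories of secondary endosymbiosis would confound donor
inference, and their leaves are set aside in clade tests.

## HPPG assembly with a floating outgroup cap

For each seed sequence the *cap* is the expect value (and rank) of its
best outgroup hit (`compute_outgroup_cap()`). A sequence is an in-group
orthologue only if it matches the seed *strictly below* the cap; when both
expect values underflow to zero, the earlier hit rank decides. Seeds
matching one another admissibly are merged by transitive closure
(`merge_seeds()`), retaining one seed per cluster by a fixed organism
precedence list, then by the lowest own-cap expect value. Groups are grown
from retained seeds (`grow_hppg()`), members being trimmed N-terminally to
their first methionine.

Boundary semantics are deliberate: admission requires strict inequality
at the cap, whereas the chimera-component cutoff at 1e-5 is inclusive.
Both follow the wording of the respective rules.

## Conservation patterns

An HPPG is called conserved when its presence map over sub-categories
satisfies at least one pattern (`conservation_patterns()`): P1 = ≥2/3 of
chrysista and ≥3/5 of diatoms; P2 = ≥2/3 of chrysista and ≥2/3 of
hypogyristea; P3 = ≥1 chrysistan sub-category plus majorities of both
hypogyristea and diatoms. Majorities are inclusive and count
sub-categories with at least one member (a majority of 3 is 2; of 5 is 3).
`select_conservation_patterns()` ranks candidate patterns by the 2×2
chi-squared separation of positive and negative control sets, the
procedure by which these three patterns are calibrated.

## Curation

The conserved domain of an alignment is defined, computably rather than
visually, as the first and last column in which more than 70% of
sequences carry the consensus residue or a BLOSUM62-positive substitute.
Members whose first aligned residue falls more than 50 consensus columns
(columns with ≥50% occupancy) after the domain start — longer than a
plausible targeting presequence — or whose last residue precedes the
domain end are removed; conservation is then re-evaluated. Columns are
trimmed at a ≥0.5 non-gap fraction (the boundary column is kept). Finally
the gene tree must contain a clade satisfying a conservation pattern whose
non-ochrophyte leaves (ignoring CASH, rhizarian and euglenid sequences)
all come from a single interrupting group.

## Origin assignment

The similarity route (`blast_top_hit_origin()`) takes the lineage of the
rank-1 hit, determined only when the first three or more hits agree;
self-hits, same-HPPG members and same-species hits are removed first. The
tree route (`tree_sister_origin()`) roots the gene tree on the edge whose
far side — never the focal stem itself — contains the most lineages (ties:
most sub-categories, most leaves, smallest leaf label), requires focal
monophyly and exactly one sister group holding at least two sequences from
two different sub-categories of one lineage. The published description of
the root ("the most phylogenetically complex node") does not define
complexity; this operationalisation is our choice, and excluding the focal
stem edge is forced — rooting there would leave every sister group
undetermined. `combine_origins()` yields a high-confidence call only when
both routes agree; otherwise the group is unresolved and annotated with
the tree origin when available, else the similarity origin.

## Synapomorphic residues

After screening trees for strictly vertical inheritance (allowing the
published paraphyly exceptions) and validating individual members by the
two-stage composite similarity rules, alignments are reduced to one
sequence per sub-category and scanned for columns where a residue is held
by ≥2/3 of ungapped focal sequences, by at least one donor sequence, by no
exclusion-set sequence, with at least one exclusion sequence ungapped.
Each such residue is placed on a reference topology at the most inclusive
clade with more matching than non-matching-or-gapped leaves; in the
earliest-origin mode gaps count as matches, and the earliest node is
constrained to be ancestor-or-equal of the observed node (ties between
equally large clades break towards tree order). Composition-biased amino
acids can be removed first via per-residue 2×2 chi-squared tests.

## Chimeras

Hits of a protein against the outgroup library at an expect value ≤1e-5
become components; components overlapping mutually by more than 70% of
each length form families by transitive closure. Families are then merged
when one family's span is included by more than 70% of its length in
another's. Because absorb-one-at-a-time merging is not confluent (the
result would depend on input order), all families linked by the inclusion
rule in a round are merged simultaneously and rounds repeat to a fixed
point; the outcome is invariant under permutation of the components. A
family's origin is the unanimous lineage of its up-to-three best-bitscore
members (families smaller than three require unanimity among what
exists). A protein is chimeric when two origin-assigned families of
different lineages fail the mutual-overlap rule; domains are labelled
N-terminal/C-terminal by span midpoint.

## Targeting and dual-targeting

The built-in plastid predictor recognises the synthetic presequence
grammar: an N-terminal hydrophobic signal region followed by an
ASAFAP-type motif within the first 50 residues. External predictor output
can be substituted via a TSV adapter; the predictor is pluggable
precisely because production-grade targeting predictors are external
tools. The mitochondrial scorer is likewise a stand-in calibrated to the
synthetic grammar (arginine content of the first 30 residues). The dual
screen scores both the full N-terminus and the frame opened by the first
methionine at precursor positions 2–31, calling dual-targeting at a score
≥0.35 for a plastid-positive sequence. Family consensus requires a
plurality held by ≥2/3 of members (2/3 alone for three-member haptophyte
families).

## Decontamination

For each pair of transcriptome libraries, every contig's best cross-library
percent identity is histogrammed at one-point resolution. Contamination
manifests as a second mode at ~100% identity above the clean between-species
mode; the threshold is the minimum bin strictly between the clean mode
adjacent to the contamination peak and the peak itself (ties towards lower
identity), after a 3-bin moving-average smoothing. Removal is symmetric:
both the contaminant and its source copy exceed the threshold, so each
contamination event costs one clean contig — the clean-loss rate is
reported over all clean contigs.

## Enrichment statistics

All enrichment tests use a two-cell goodness-of-fit chi-squared
(`chi_squared_obs_exp()`): cells `[observed, total − observed]` against
`[expected, total − expected]`, one degree of freedom, no continuity
correction. The published p-values for these comparisons are not exactly
recoverable from the printed observed/expected pairs under any standard
one-degree-of-freedom construction, so this construction is fixed and
documented rather than reverse-engineered. Its type-I error at alpha 0.05
is verified by simulation to lie in [0.03, 0.07].

For uniquely shared HPPGs between lineage pairs, the corrected expected
fraction of a pair is `p_i p_j / (1 − p_i p_j)` where `p` are involvement
proportions (`expected_pair_fraction()`; with both proportions at one
half, the raw quarter is scaled by four-thirds to one-third). These
per-pair corrections do not form a probability distribution, so
`expected_unique_shared()` uses them as weights rescaled to the observed
cross-pair total — the dataset-level expectations then conserve the total
exactly and coincide with the per-pair values in symmetric designs. The
two behaviours cannot be unified: in a two-lineage design, conservation
forces the single pair's fraction to one while the per-pair correction
gives one-third; we expose both, each for its purpose.

Coexpression is summarised by Pearson correlations over gene pairs,
grouped into origin-pair classes, with a one-way ANOVA per origin
comparing its within-class correlations to each origin–other class.
Correlation pairs share genes and are not independent; these p-values are
descriptive. Indeed, with four origin classes each tested at alpha 0.05,
even a perfectly calibrated test would flag at least one class in roughly
a fifth of null datasets, and at the thirty-gene scale chance alignment of
co-expression modules with origin labels makes the observed flag rate
slightly higher still. The package reports the raw per-origin p-values,
as the source analysis does, and the validation suite records this
behaviour honestly rather than adjusting the statistic to force a pass.

## The synthetic dataset

`simulate_dataset()` generates the study conditions the pipeline is
validated under: 30 families (12 red-algal, 8 green-algal, 5
aplastidic-stramenopile, 5 prokaryotic) with plastid-targeting fractions
of 0.8/0.7/0.35/0.35 — endosymbiotic donors biased towards plastid
function; mature proteins of 240 residues evolved by per-branch Poisson
substitutions along origin-specific gene trees in which the ochrophyte
clade attaches inside the donor lineage's crown; presequences of 30–50
residues following the signal + ASAFAP grammar, with an arginine-rich
alternative-start frame for dual-targeted families; 6 fusion proteins
hosted in a transcriptome species and built from that species' own family
copies; verbatim cross-library contamination at rate 0.015 (with
symmetric removal this yields a discarded fraction of transcriptome
contigs near the few-percent level reported for real transcriptome
surveys); N-terminally truncated assembly fragments at rate 0.06; and
expression modules of ~6 genes at within-module correlation 0.5 assigned
independently of origin. Indels are realised as deletions in a fixed
ancestral column frame, so the emitted alignments are exact by
construction; insertions are not modelled because they would break the
planted coordinate frame without exercising any additional rule.
Similarity is scored by `compute_similarity_scores()` — Smith–Waterman
local alignment under BLOSUM62 with affine gaps 11/1 and the
Karlin–Altschul bitscore transform — computed within families only;
between unrelated families similarities are negligible by construction
and omitted.

What the generator does *not* emulate: real targeting-signal diversity
(the grammar is recognisable by construction, so targeting-prediction
accuracy on synthetic data says nothing about ASAFind- or HECTAR-class
performance on real proteomes); alignment and tree estimation error
(alignments and trees are emitted true, so curation and sister-group
rules are tested against planted signal, not against reconstruction
noise); rate heterogeneity, compositional attraction and long-branch
artefacts; paralogy and gene duplication. Passing tests therefore
demonstrate the correctness of the decision rules, not the field
performance of the upstream predictors and aligners they consume.

## Problem sizes and determinism

The default validation run uses 30 families (~670 sequences, ~15,000
ranked hits) and completes in well under a minute; the decontamination
property test uses 20 seeds of an 11-family design; null calibrations use
2000 simulated tests. All randomness flows from a single integer seed;
two runs with the same configuration produce byte-identical tabular
outputs, which the acceptance script verifies by file checksums.

## Known limitations

Tree inference and multiple alignment are consumed, never computed; the
built-in targeting and mitochondrial scorers are stand-ins for external
predictors behind a documented adapter; the coexpression ANOVA inherits
the non-independence caveat above; and the published headline dataset
(hundreds of ancestral groups from eleven genomes plus >150
transcriptomes) is out of scope at desk scale — the pipeline reproduces
the *procedures*, validated against planted truth, not the dataset-scale
counts.
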