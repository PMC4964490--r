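---
title: "Methods: structural annotation of HMW glutenin subunit genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation of HMW glutenin subunit genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmwgs)
```

# The problem

High-molecular-weight glutenin subunits (HMW-GSs) share a rigid
four-part architecture: a cleaved signal peptide, a conserved
N-terminal domain, a long central repetitive domain built from a tiny
peptide vocabulary, and a conserved C-terminal domain. Alleles cloned
from wild Triticeae differ from the wheat prototypes in ways that are
individually small but analytically awkward: whole-motif indels change
the repeat length, point substitutions create premature stop codons,
single-base deletions near the C-terminus shift the reading frame, and
the diagnostic features that separate x-type from y-type subunits can
disagree with each other. `hmwgs` turns the conventional manual
characterization of such genes into a reproducible pipeline, and pairs
it with a generator of synthetic genes with exact ground truth so that
every stage is testable offline.

This vignette records the modelling choices, their parameters, and the
limits of what the test suite demonstrates.

# ORF analysis

The ORF is anchored at the first `ATG` and scanned codon-wise under the
standard nuclear genetic code; `TAA`, `TAG` and `TGA` are the stop set.
Two accounting conventions matter for this family:

* **Tandem terminal stops.** These genes end in two consecutive stop
  codons (they are encoded by the cloning primer), so terminal stops
  are counted as the maximal run of consecutive stop codons in the
  frame anchored at the 3' end of the sequence. Anchoring at the 3'
  end, not at the ATG, keeps the count correct for frameshifted
  pseudogenes, in which the terminal stops are out of frame relative to
  the start codon. An intact gene of $R$ residues then satisfies
  $\mathrm{length_{nt}} = 3(R + 2)$ exactly.
* **Premature stops** are in-frame (ATG-frame) stop codons ending
  before the terminal run; a record is *intact* iff it has none and its
  length from the ATG is a codon multiple.

Frameshifts are localized by global nucleotide alignment of the query
against an intact reference. Every single-nucleotide gap in the query
row whose downstream net frame offset stays non-zero (checked over the
following 30 alignment columns, i.e. not compensated locally) is
reported as a frameshift event. Because gap placement inside
homopolymer runs is ambiguous, all gap runs are first shifted to their
leftmost score-equivalent position; the reported coordinate — the
1-based query position of the base following the deletion — is
therefore deterministic, and the generator computes its expected value
under the same convention. Pseudogenes are then re-annotated on the
*conceptual translation*: one `N` is re-inserted at each detected
deletion (the affected codon translates `X`), premature stops are
carried through as `*`, and the annotation is flagged `reconstructed`.
This mirrors the conventional practice of reporting pseudogene domain
sizes from the inferred ancestral frame. A frameshifted gene without a
reference cannot be frame-corrected and fails segmentation with a
diagnostic rather than returning a silently wrong C-terminal domain.

# Domain segmentation

Boundaries come from family anchors rather than de novo prediction:

1. **Signal/N:** the better-scoring of the two signal-peptide templates
   (21-aa canonical; 18-aa variant of the hexapeptide-deleted lineage)
   is located inside the first 30 residues by pattern-global alignment;
   the boundary is the template's end. A best score under
   `signal_min_identity` (0.6 of the maximum) or a non-18/21 length
   flags the record `atypical`.
2. **N/repetitive:** immediately after the first occurrence of the
   terminal hexapeptide `SSQ[PT]VQ` (exact match, falling back to the
   first 6-mer within edit distance 1); absence is a hard segmentation
   error, since nothing else reliably separates the N-terminal domain
   from the glutamine-rich repeats.
3. **Repetitive/C:** the suffix length in 30–54 whose global alignment
   against the 42-aa C-terminal consensus scores best, requiring at
   least `cterm_min_identity` (0.5) of the maximum score.

Anchor matching is alignment-based (+2 match, −1 mismatch, affine gaps)
so single substitutions inside an anchor do not break segmentation. The
anchors ship as an editable FASTA file (`inst/extdata/anchor_templates.fa`);
the bundled templates are *synthetic consensus sequences* that honour
the family's documented anchor features (five N-terminal cysteines, the
extra-glutamine column, the terminal hexapeptides, `LAAQLPAMCRL`, one
C-terminal cysteine) without being any real gene's residues. Users
working from real alignments can substitute their own consensus.

"Near the C-terminus of the repetitive domain", used by the cysteine
placement diagnostic, is quantified as the final 60 residues
(`repeat_terminal_window`); the family's known y-type cysteine
placements fall well inside this window, and the value is exposed in
the configuration. Whether the extra glutamine is counted inside the
102/105-residue N-terminal totals is deliberately left to the
boundaries: lengths are derived from anchor positions only.

# Motif-grammar decomposition

The repetitive domain is tiled by dynamic programming over the template
library `{GQQ, PGQGQQ, GYYPTSPQQ, PGGQQ, GYYPTSPHQQ}`. A segment of
length within $\pm t$ of a template (class threshold $t$: 1 for the
tripeptide, 2 for hexa/penta, 3 for nona/deca) and edit distance
$\le t$ may carry that class at cost equal to its edit distance;
residues left outside any class cost `motif_other_penalty` (1.0) each
and merge into maximal `other` runs. Standalone `GQQ` tiles carry a
small surcharge (`motif_tri_bias`, 0.25) so hexa/nona tilings win
cost ties — the tripeptide is an x-type-associated element that should
not shadow hexapeptide copies. Ties are then broken by fewest segments,
then longest motif, making the tiling deterministic. The concatenation
of segments always equals the input (lossless), with the degenerate
worst case being a single `other` run.

The DP cost is checked against an independent memoized enumeration of
all tilings on strings up to 24 residues, and losslessness is
property-tested on arbitrary strings.

The two phylogeny regions are sliced by segment count: the
signal-stripped N-terminal plus the first 3 segments, and the last 6
segments plus the C-terminal domain. The "motif" unit is the DP
segment, irregular segments included; the counts (3 and 6) are
configuration values, since the delimitation of "the first three
motifs" is a convention, not something the data dictate.

# Type classification

Seven binary diagnostics are evaluated, each pointing to x or y (see
`?classify_subunit_type`); they are combined by an equal-weight vote:
unanimity gives `x` or `y`, a strict majority gives `intermediate_x` /
`intermediate_y`, a tie is `unclassified`. Equal weighting is the
least-assumptive reading of a feature list that the literature argues
qualitatively; the rule is a pure function of the direction vector
(`type_vote()`), exhaustively testable over all $2^7$ inputs. The
extra-glutamine diagnostic is read off an alignment column against the
N-terminal template rather than an absolute index, because indels shift
positions; the marker records the *first* glutamine of the run so that
leftmost gap normalization makes presence/absence well defined.

# Pairwise variation

Global nucleotide alignment uses +2/−1 with gap opening 6 and gap
extension 0.5 per base. The stiff opening cost keeps whole motif-block
indels (18–63 nt) in single gap runs instead of fragmenting them into
mismatch patches; the values are configurable. SNPs are aligned columns
with two different bases — columns inside gap runs are never SNPs —
and indels are maximal gap runs with leftmost-normalized coordinates.
Terminal stop codons are part of the aligned region, as gene lengths in
this family conventionally include them. An alignment whose aligned
bases are less than `divergence_floor` (0.75) identical is refused as
too divergent to interpret. At the amino-acid layer, restricted to the
repetitive domain, substitution columns count only residue-vs-residue
differences: columns containing `-`, `*` or `X` are excluded, so a
premature stop in one pseudogene does not inflate the substitution
count. Group comparison matches indels across pairs by length and
extra-side sequence and names them `Indel1, Indel2, ...` by descending
length, so the same physical indel carries one name everywhere.

# Phylogeny

The analysis regions are aligned progressively: a single-linkage guide
from pairwise identities, then profile–profile alignment with
sum-of-pairs column scores and affine gaps (open 4, extend 1 in
column-score units), implemented in C++ for speed with a fixed
tie-break order so results are platform-independent. Distances are p or
Poisson-corrected ($-\ln(1-p)$) over pairwise-deleted (shared non-gap)
columns — complete deletion would discard most columns whenever repeat
numbers vary. Trees come from neighbor joining (`ape::nj`), rooted on
the outgroup; supports are percentages of nonparametric bootstrap
replicates (columns resampled under a fixed seed) containing each
internal split. Taxa are put in canonical order before tree building,
so topology and supports do not depend on input order even when
zero-distance ties occur. Group assignment gives each query the group
of the smallest clade containing it and at least one reference,
provided that clade's references are unanimous.

The package deliberately implements a distance-based reconstruction,
not maximum likelihood: for this family the reproducible claims are
topology-level (which genes form which clades), and those are what the
acceptance surface checks. Published support values from
likelihood analyses are not comparable quantities and are not asserted
anywhere.

# The synthetic generator and the study-design family

`generate_family()` assembles genes from the anchor templates and a
motif arrangement, reverse-translates with one fixed codon per residue
(a frequent-wheat-codon table; determinism is worth more here than
codon-usage realism), and appends the tandem stops `TGA TAG`. Planted
mutations record exact coordinates: SNPs avoid creating in-frame stops,
motif-block indels are whole-motif (1–3 motifs, 18–63 nt, always frame
preserving), in-frame stops are restricted to the repetitive domain and
single-base deletions to the C-terminal domain — the lesion classes
seen in this gene family's pseudogenes.

`simulate_roegneria_family()` is a fully synthetic stand-in for the six
cloned genes. It plants, by construction: the two lineages (18/102
`SSQPVQ` vs 21/105 `SSQTVQ`, separated additionally by fixed template
substitutions across all domains, as two diverged St genomes); repeat
lengths of 293/320/299 and 250/259/238 residues, giving intact ORFs of
1371/1452/1389 bp; the pairwise design 6/15/11 SNPs with the 63-nt and
18-nt indels in lineage 1 and 8/4/8 SNPs with the 27-nt and 36-nt
indels in lineage 2 (16 and 10 distinct SNPs per triad, repeat-domain
amino-acid substitutions 2/5/5 and 2/1/3); two/one/two premature stops;
and a single-base deletion at the first base of C-terminal codon 34 of
each lineage-2 gene. Free coordinates (SNP placement) are seeded; the
design counts are fixed. The stand-in is synthetic sequence — only its
planted *structure* matches the real accessions, which is exactly what
the pipeline is supposed to recover. Real accessions in FASTA or
GenBank flat-file format go through the same `read_gene_sequences()` →
`annotate_family()` path.

`simulate_two_cluster_family()` generates the planted-partition setting
for tree recovery: two templates separated by fixed substitutions
across the N-terminal domain and the repetitive domain (including the
first and last motifs, which enter the analysis regions), each with
three members carrying two private repetitive-domain SNPs, plus a
divergent outgroup. The design keeps within-cluster variation well
below the between-cluster signal *inside the analysis regions* — the
regime the recovery property is about; an earlier design that separated
the clusters only inside the repeats left the N-side region nearly
uninformative and recovered the split in only ~94% of families.

What the generator does **not** emulate: real codon usage and
base composition, sequencing error, branch-length-calibrated
substitution processes, and repeat turnover by unequal crossing over.
Passing tests therefore demonstrate that the algorithms recover planted
structure exactly under the family's architecture, not that anchors or
thresholds are optimal for every real divergent allele; for real data
the anchors file and the configuration are the adjustment points.

# Numerical choices and degenerate inputs

* Alignment scores: nt +2/−1, gaps 6 + 0.5/base; aa +2/−1 with the same
  gap costs; identity computed over aligned (non-gap) columns.
* All gap runs leftmost-normalized before coordinates are read off.
* Decomposition: per-residue `other` penalty 1.0, tripeptide bias 0.25,
  class thresholds 1/2/2/3/3; ties by fewest segments then longest
  motif.
* Distances: Poisson correction errors out at $p \ge 1$ rather than
  returning infinity; taxon pairs with zero shared columns are errors.
* Empty inputs error early and loudly (empty sequence, empty bundle
  list, empty repetitive domain, fewer than 3 sequences to align,
  fewer than 6 segments to slice).
* Problem sizes in the shipped tests and acceptance script: 100-seed
  property loops, 500 random pairs for the alignment oracle, 8-leaf
  trees for additivity, 500 bootstrap replicates, seven-taxon families
  — sizes chosen so the full suite exercises every claim at the scale
  the analyses actually run at.

# Known limitations

* Segmentation presumes the family architecture; a gene without the
  terminal hexapeptide or a recognizable C-terminal consensus is an
  error by design, not a soft call.
* Frameshift detection targets single-base deletions (this family's
  lesion); multi-base frameshifts would need the convention extended.
* The x/y vote treats all seven features equally; with real borderline
  alleles the evidence table, not the label alone, is the result to
  read.
* Neighbor joining with bootstrap is not a substitute for model-based
  phylogenetics when branch support on deep splits is the question.
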