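# hmwgs

Structural annotation and evolutionary grouping of high-molecular-weight
glutenin subunit (HMW-GS) genes.

HMW-GSs are the seed storage proteins that dominate the viscoelastic
behaviour of wheat dough. Each *Glu-1* locus carries a pair of genes
encoding one x-type and one y-type subunit, and the wild relatives of
wheat (here, *Roegneria* and other St-genome Triticeae) harbour novel,
often atypical alleles: shorter coding regions, pseudogenes with
in-frame stop codons and frameshifts, and subunits whose diagnostic
features mix x- and y-type characters. `hmwgs` is a pipeline for
characterizing such genes from their cloned coding sequences:

* **ORF / pseudogene analysis** — ORF anchored at the first ATG, codon
  scan with the standard genetic code, terminal *tandem stop codons*
  (the maximal run of consecutive stops in the 3'-anchored frame)
  counted separately from premature in-frame stops; an intact gene of
  *R* residues satisfies `length_nt = 3(R + 2)`. Single-base-deletion
  frameshifts are localized by global nucleotide alignment (affine
  gaps, leftmost-normalized gap placement) against an intact reference,
  and pseudogenes are re-annotated on the frame-corrected conceptual
  translation.
* **Four-domain segmentation** — signal peptide (18/21 aa), N-terminal
  (102/105 aa), central repetitive and C-terminal (42 aa) domains,
  delimited by family anchors: the signal-peptide consensus, the
  terminal hexapeptide `SSQ[PT]VQ` closing the N-terminal domain, and
  the C-terminal consensus carrying the undecapeptide `LAAQLPAMCRL`.
  Per-domain cysteine censuses reproduce the conventional table layout.
* **Motif-grammar decomposition** — the repetitive domain is tiled
  losslessly into classified segments by a dynamic program minimizing
  total edit distance to the template library `{GQQ, PGQGQQ,
  GYYPTSPQQ, PGGQQ, GYYPTSPHQQ}`, with a per-residue penalty for
  unmatched runs; a variant copy such as `PEQGQQ` is classified as a
  hexapeptide at edit distance 1.
* **x/y-type classification** — seven discrete diagnostics (N-terminal
  length class, five N-terminal cysteines, terminal hexapeptide, extra
  glutamine, `LAAQLPAMCRL`, repeat-terminal cysteine placement,
  standalone GQQ tiles) combined by an equal-weight vote into `x`, `y`,
  or an intermediate call inclining to the majority side.
* **Pairwise variation** — SNP columns and maximal gap runs from global
  alignment, stable `Indel1, Indel2, ...` naming across a gene group,
  plus the amino-acid substitution layer of the repetitive domain.
* **Two-region phylogeny** — the N-terminal plus the first three repeat
  motifs, and the last six motifs plus the C-terminal, aligned by a
  deterministic progressive aligner, with p- or Poisson-corrected
  distances (pairwise gap deletion), neighbor joining, nonparametric
  bootstrap over columns, and clade-based group assignment against
  reference subunits.
* **Synthetic data** — `generate_family()` emits HMW-GS-like genes with
  exact ground truth (domain boundaries, motif tiling, planted SNPs,
  whole-motif indels of 18-63 nt, in-frame stops, single-base
  C-terminal deletions), so every stage is testable without downloads;
  `simulate_roegneria_family()` is a synthetic stand-in family whose
  planted design reproduces the published six-gene architecture.

## Worked example

```r
library(hmwgs)

fam <- simulate_roegneria_family(seed = 1)
bundles <- annotate_family(fam$genes[1:6], reference = "Rny1")
domain_table(bundles)[, c("gene", "orf_bp", "signal_len", "n_terminal_len",
                          "repetitive_len", "c_terminal_len", "total_cys",
                          "intact", "type")]
```

```
  gene orf_bp signal_len n_terminal_len repetitive_len c_terminal_len total_cys intact           type
1 Rny1   1371         18            102            293             42         6   TRUE intermediate_y
2 Rny2   1259         21            105            250             42         6  FALSE intermediate_y
3 Rny3   1452         18            102            320             42         6   TRUE intermediate_y
4 Rny4   1286         21            105            259             42         6  FALSE intermediate_y
5 Ray1   1389         18            102            299             42         6   TRUE intermediate_y
6 Ray2   1223         21            105            238             42         6  FALSE intermediate_y
```

Each row is the conventional per-gene summary: ORF size in bp including
the tandem stop codons, per-domain residue counts (pseudogenes are
reported on their frame-corrected translation and flagged not intact),
the six-cysteine census, and the type call — all six subunits are
intermediates inclining to the y-type. Pairwise variation inside the
intact lineage:

```r
r <- compare_pair(fam$genes$Rny1, fam$genes$Rny3,
                  bundle_a = bundles$Rny1, bundle_b = bundles$Rny3)
r
#> <variation_report> Rny1 vs Rny3: 6 SNP(s), 2 indel(s)
#>   Indel1: 63 nt (b_has_extra, 544-606)
#>   Indel2: 18 nt (b_has_extra, 876-893)
#>   repetitive-domain aa substitutions: 2
```

The 63-nt and 18-nt blocks are whole-motif indels (21 and 6 residues);
`compare_group()` keeps their names consistent across all pairs of the
triad. A bootstrap neighbor-joining tree of the N-side analysis region
then splits the six genes into the two planted lineages:

```r
regions <- vapply(annotate_family(fam$genes, reference = "Rny1"),
                  function(b) slice_flanking_regions(b$annotation,
                    b$decomposition, b$translation)$n_region, character(1))
tree <- build_tree(align_regions(regions), model = "poisson",
                   bootstrap_n = 500, outgroup = "Dhord", seed = 11)
clade_is_monophyletic(tree, c("Rny1", "Rny3", "Ray1"))  # TRUE
clade_is_monophyletic(tree, c("Rny2", "Rny4", "Ray2"))  # TRUE
```

A thin command-line wrapper (`inst/cli/hmwgs-cli.R`) exposes the same
stages as `annotate`, `compare`, `tree` and `simulate` subcommands.

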