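# Preset simulations.
#
# simulate_roegneria_family() builds a fully synthetic six-gene family
# whose printed architecture (domain sizes, SNP/indel pattern, pseudogene
# lesions, two-lineage structure) matches the published summary of the
# six Roegneria HMW-GS genes, plus a divergent D-hordein-like outgroup.
# The sequences are NOT the deposited accessions -- they are assembled
# from the package's synthetic anchor templates -- but every structural
# quantity the pipeline is meant to recover is planted exactly, with the
# design recorded in the returned ground truth.

insert_nt <- function(s, after, ins) {
  paste0(substr(s, 1L, after), ins, substr(s, after + 1L, nchar(s)))
}

delete_nt <- function(s, from, to) {
  paste0(substr(s, 1L, from - 1L), substr(s, to + 1L, nchar(s)))
}

# single-base codon edits used to plant synonymous / nonsynonymous SNPs
# (third-position swap keeps the residue; first-position swap changes it
# without ever creating a stop codon or a cysteine)
syn_third <- c(CCA = "CCG", GGC = "GGT", CAA = "CAG", TAC = "TAT",
               ACC = "ACT", TCC = "TCT")
nonsyn_first <- c(CCA = "GCA", GGC = "AGC", CAA = "GAA", TAC = "AAC",
                  ACC = "GCC", TCC = "GCC")

# apply a planted SNP at repeat-amino-acid ordinal `a` (1-based, shared
# block coordinates); `off` is the gene's repetitive-domain nt offset
plant_snp <- function(s, off, a, residue, kind) {
  codon <- wheat_codon_table()[[residue]]
  new <- if (kind == "syn") syn_third[[codon]] else nonsyn_first[[codon]]
  if (is.null(new)) stop("no planned edit for codon ", codon)
  pos_in_codon <- which(strsplit(codon, "")[[1]] != strsplit(new, "")[[1]])
  p <- off + 3L * (a - 1L) + pos_in_codon
  apply_substitution(s, p, substr(new, pos_in_codon, pos_in_codon))
}

# residue-level divergence map for the synthetic outgroup: never emits
# C or V, never maps a residue to itself
divergence_map <- c(A = "T", R = "K", N = "S", D = "E", Q = "H", E = "D",
                    G = "A", H = "Q", I = "L", K = "R", L = "I", M = "I",
                    F = "Y", P = "S", S = "N", T = "A", W = "F", Y = "F",
                    V = "I", C = "C")

diverge_protein <- function(protein, positions) {
  chars <- strsplit(protein, "")[[1]]
  positions <- positions[positions <= length(chars)]
  positions <- positions[chars[positions] != "C"]
  chars[positions] <- divergence_map[chars[positions]]
  paste(chars, collapse = "")
}

#' Simulate the six-gene study family (synthetic stand-in)
#'
#' Builds a synthetic family of six HMW-GS genes in two lineages of
#' three, reproducing the published structural design of the Roegneria
#' genes: lineage 1 (Rny1, Rny3, Ray1) with the 18-aa signal peptide,
#' 102-aa N-terminal ending SSQPVQ and intact ORFs of 1371/1452/1389 bp;
#' lineage 2 (Rny2, Rny4, Ray2) with the 21-aa signal, 105-aa N-terminal
#' ending SSQTVQ, planted in-frame stop codons (2/1/2) in the repetitive
#' domain and a single-base deletion at the 34th C-terminal codon of
#' each gene. Pairwise variation is planted exactly: 6/15/11 SNPs with
#' the 63-nt Indel1 and 18-nt Indel2 inside lineage 1; 8/4/8 SNPs with
#' the 27-nt Indel3 and 36-nt Indel4 inside lineage 2; repetitive-domain
#' amino-acid substitution counts 2/5/5 and 2/1/3. A divergent
#' D-hordein-like synthetic outgroup can be appended for tree rooting.
#'
#' The gene sequences are synthetic (assembled from the package's anchor
#' templates); only the planted structure, not the residue identity,
#' matches the real accessions.
#'
#' @param seed RNG seed; controls the free coordinates (SNP placement),
#'   not the design counts.
#' @param include_outgroup append the synthetic outgroup record.
#' @param anchors an `anchor_set`.
#' @return `list(genes =, truth =)` where `genes` is a named list of
#'   `gene_record`s and `truth` records the full design: the per-gene
#'   domain table, premature stop counts, expected frameshift event
#'   positions, the pairwise SNP/indel/aa-substitution design, and the
#'   two-lineage grouping.
#' @export
simulate_roegneria_family <- function(seed = 1L, include_outgroup = TRUE,
                                      anchors = default_anchors()) {
  with_seed(seed, function() {
    tmpl <- motif_templates()
    block1 <- rep(c("hexa", "hexa", "nona"), 3)             # 63 aa
    block2 <- c("hexa", "irregular_penta", "hexa", "nona",
                "hexa", "hexa", "nona")                      # 47 aa
    run <- c("nona", "nona", "nona", "hexa", "irregular_deca") # 43 aa
    pair <- c("hexa", "hexa")                                # 12 aa
    block4 <- c(rep(c("hexa", "hexa", "nona"), 5),
                "irregular_penta", rep("hexa", 3))           # 128 aa
    arr1 <- c(block1, block2, run, pair, block4)             # 293 aa
    arr2 <- c(block1, block2, pair, block4)                  # 250 aa
    stopifnot(sum(nchar(tmpl[arr1])) == 293L,
              sum(nchar(tmpl[arr2])) == 250L)

    parts1 <- list(signal = anchors$signal$short18,
                   n_terminal = anchors$n_terminal$aa102$sequence,
                   arrangement = arr1, c_terminal = anchors$c_terminal)
    base1 <- assemble_gene(parts1)$sequence
    # lineage 2 template: beyond the hexapeptide deletion and the
    # SSQTVQ/SSQPVQ exchange, the two lineages (the two St genomes)
    # carry fixed substitutions across the N-terminal, repetitive and
    # C-terminal domains; placed outside the block that hosts the
    # planted SNPs and lesions so the pairwise design stays exact
    n105_div <- diverge_protein(anchors$n_terminal$aa105$sequence,
                                c(8L, 17L, 30L, 44L, 64L, 75L, 85L, 93L))
    rep2_div <- diverge_protein(repeat_from_arrangement(arr2),
                                c(150L, 170L, 190L, 230L, 245L))
    c42_div <- diverge_protein(anchors$c_terminal, c(3L, 8L, 14L, 37L))
    prot2 <- paste0(anchors$signal$long21, n105_div, rep2_div, c42_div)
    base2 <- paste0(reverse_translate(prot2), "TGATAG")
    off1 <- 3L * 120L   # repetitive-domain nt offset, lineage 1
    off2 <- 3L * 126L   # lineage 2

    block1_aa <- repeat_from_arrangement(block1)

    # ---- lineage 1: Rny1 (base), Rny3 (+Indel1 +Indel2), Ray1 (+Indel2)
    indel1_aa <- "PEQGQQGYYPTSPQQPGKGQQ"
    indel2_aa <- "PGQGQQ"
    ins1_at <- off1 + 3L * 63L    # after block1
    ins2_at <- off1 + 3L * 165L   # after the hexa pair
    rny3 <- insert_nt(base1, ins2_at, reverse_translate(indel2_aa))
    rny3 <- insert_nt(rny3, ins1_at, reverse_translate(indel1_aa))
    ray1 <- insert_nt(base1, ins2_at, reverse_translate(indel2_aa))

    # SNP design: |A|=6 on Rny3, |B|=15 on Ray1, 5 shared identical;
    # nonsynonymous counts 2 (Rny1-Rny3), 5 (Rny1-Ray1), 5 (Rny3-Ray1)
    ords1 <- sample(1:63, 16L)
    shared1 <- ords1[1:5]      # 1 nonsyn + 4 syn
    a_only <- ords1[6]         # nonsyn
    b_only <- ords1[7:16]      # 4 nonsyn + 6 syn
    kind1 <- c("nonsyn", rep("syn", 4))
    kindB <- c(rep("nonsyn", 4), rep("syn", 6))
    res_at <- function(a) substr(block1_aa, a, a)
    for (i in seq_along(shared1)) {
      rny3 <- plant_snp(rny3, off1, shared1[i], res_at(shared1[i]), kind1[i])
      ray1 <- plant_snp(ray1, off1, shared1[i], res_at(shared1[i]), kind1[i])
    }
    rny3 <- plant_snp(rny3, off1, a_only, res_at(a_only), "nonsyn")
    for (i in seq_along(b_only)) {
      ray1 <- plant_snp(ray1, off1, b_only[i], res_at(b_only[i]), kindB[i])
    }

    # ---- lineage 2: Rny2 (base + 2 stops), Rny4 (+Indel3, 1 stop),
    #      Ray2 (-Indel4, 2 stops); all three frameshifted at C-terminal
    #      codon 34
    stop_sites <- c(30L, 51L)   # glutamine codons in block1 -> CAA>TAA
    plant_stop <- function(s, a) apply_substitution(s, off2 + 3L * (a - 1L) + 1L, "T")
    ins3_at <- off2 + 3L * 69L            # after the 10th segment
    del4_from <- off2 + 3L * 110L + 1L    # the hexa pair, aa 111-122
    del4_to <- off2 + 3L * 122L

    ords2 <- sample(setdiff(1:63, stop_sites), 9L)
    shared2 <- ords2[1:2]       # syn, carried by Rny4 and Ray2
    a2_only <- ords2[3:7]       # Rny4: 2 nonsyn + 3 syn
    b2_only <- ords2[8:9]       # Ray2: 1 nonsyn + 1 syn
    kindA2 <- c(rep("nonsyn", 2), rep("syn", 3))
    kindB2 <- c("nonsyn", "syn")

    rny2 <- base2
    rny4 <- insert_nt(base2, ins3_at, reverse_translate("QGYYPTSPQ"))
    ray2 <- delete_nt(base2, del4_from, del4_to)
    for (a in shared2) {
      rny4 <- plant_snp(rny4, off2, a, res_at(a), "syn")
      ray2 <- plant_snp(ray2, off2, a, res_at(a), "syn")
    }
    for (i in seq_along(a2_only)) {
      rny4 <- plant_snp(rny4, off2, a2_only[i], res_at(a2_only[i]), kindA2[i])
    }
    for (i in seq_along(b2_only)) {
      ray2 <- plant_snp(ray2, off2, b2_only[i], res_at(b2_only[i]), kindB2[i])
    }
    rny2 <- plant_stop(plant_stop(rny2, stop_sites[1]), stop_sites[2])
    rny4 <- plant_stop(rny4, stop_sites[1])
    ray2 <- plant_stop(plant_stop(ray2, stop_sites[1]), stop_sites[2])

    # single-base deletion at the first base of C-terminal codon 34
    frameshift <- list()
    del_at_codon34 <- function(s, c_off_aa, id) {
      p <- 3L * (c_off_aa + 33L) + 1L
      frameshift[[id]] <<- list(planted = p,
                                expected = leftmost_deletion_pos(s, p))
      delete_nt(s, p, p)
    }
    rny2 <- del_at_codon34(rny2, 376L, "Rny2")
    rny4 <- del_at_codon34(rny4, 385L, "Rny4")
    ray2 <- del_at_codon34(ray2, 364L, "Ray2")

    src <- "simulate_roegneria_family (synthetic stand-in)"
    genes <- list(
      Rny1 = gene_record("Rny1", base1, source = src),
      Rny2 = gene_record("Rny2", rny2, source = src),
      Rny3 = gene_record("Rny3", rny3, source = src),
      Rny4 = gene_record("Rny4", rny4, source = src),
      Ray1 = gene_record("Ray1", ray1, source = src),
      Ray2 = gene_record("Ray2", ray2, source = src)
    )

    if (include_outgroup) {
      arrO <- c(rep(c("hexa", "nona"), 10), "irregular_penta",
                "irregular_deca", "irregular_penta", rep("hexa", 5)) # 200 aa
      partsO <- list(signal = anchors$signal$long21,
                     n_terminal = anchors$n_terminal$aa105$sequence,
                     arrangement = arrO, c_terminal = anchors$c_terminal)
      protO <- assemble_gene(partsO)$protein
      n_pos <- 21L + c(8L, 17L, 26L, 35L, 44L, 62L, 71L, 80L, 89L)
      n_pos <- n_pos[!(n_pos %in% (21L + 50L:60L))]
      rep_pos <- seq(127L, 326L, by = 7L)
      c_pos <- 326L + c(3L, 8L, 13L, 18L, 36L, 39L)
      protO <- diverge_protein(protO, c(c(4L, 9L, 14L), n_pos, rep_pos, c_pos))
      genes$Dhord <- gene_record(
        "Dhord", paste0(reverse_translate(protO), "TGATAG"),
        source = "synthetic D-hordein-like outgroup")
    }

    table_truth <- data.frame(
      gene = c("Rny1", "Rny2", "Rny3", "Rny4", "Ray1", "Ray2"),
      lineage = c(1L, 2L, 1L, 2L, 1L, 2L),
      orf_bp = vapply(c("Rny1", "Rny2", "Rny3", "Rny4", "Ray1", "Ray2"),
                      function(g) nchar(genes[[g]]$sequence), integer(1)),
      signal_len = c(18L, 21L, 18L, 21L, 18L, 21L),
      n_terminal_len = c(102L, 105L, 102L, 105L, 102L, 105L),
      repetitive_len = c(293L, 250L, 320L, 259L, 299L, 238L),
      c_terminal_len = 42L,
      cys_n_terminal = 5L, cys_repetitive = 0L, cys_c_terminal = 1L,
      cys_total = 6L,
      is_pseudogene = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE),
      stringsAsFactors = FALSE
    )
    table_truth$total_len <- with(table_truth,
      signal_len + n_terminal_len + repetitive_len + c_terminal_len)

    pairwise <- data.frame(
      a = c("Rny1", "Rny1", "Rny3", "Rny2", "Rny2", "Rny4"),
      b = c("Rny3", "Ray1", "Ray1", "Rny4", "Ray2", "Ray2"),
      snps = c(6L, 15L, 11L, 8L, 4L, 8L),
      indel_lengths = I(list(c(63L, 18L), 18L, 63L, 27L, 36L, c(36L, 27L))),
      aa_subs_repetitive = c(2L, 5L, 5L, 2L, 1L, 3L),
      stringsAsFactors = FALSE
    )

    truth <- list(
      table = table_truth,
      premature_stops = c(Rny1 = 0L, Rny2 = 2L, Rny3 = 0L, Rny4 = 1L,
                          Ray1 = 0L, Ray2 = 2L),
      frameshift = frameshift,
      pairwise = pairwise,
      indel_lengths = c(Indel1 = 63L, Indel2 = 18L, Indel3 = 27L,
                        Indel4 = 36L),
      groups = list(st_group_1 = c("Rny1", "Rny3", "Ray1"),
                    st_group_2 = c("Rny2", "Rny4", "Ray2"),
                    outgroup = if (include_outgroup) "Dhord" else NULL)
    )
    list(genes = genes, truth = truth)
  })
}

#' Simulate a two-cluster gene family for planted-partition recovery
#'
#' Two templates (the two signal/N-terminal lineages with different
#' motif arrangements, separated further by a fixed set of planted
#' template substitutions spread across the repetitive domain) each
#' yield `n_per_cluster` members carrying a few private repetitive-domain
#' SNPs, plus a divergent outgroup. Used to test that the two-region
#' neighbor-joining tree recovers the planted split.
#'
#' @param seed RNG seed.
#' @param n_per_cluster members per cluster.
#' @param snps_within private SNPs per member.
#' @param anchors an `anchor_set`.
#' @return `list(genes =, clusters =, outgroup =)`; `genes` is a named
#'   list of `gene_record`s (`A1..`, `B1..`, `OUT`), `clusters` a named
#'   list of the two member-id vectors.
#' @export
simulate_two_cluster_family <- function(seed = 1L, n_per_cluster = 3L,
                                        snps_within = 2L,
                                        anchors = default_anchors()) {
  with_seed(seed, function() {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
    mk_muts <- function(n) rep(list(list(mutation_spec("snp",
                                                       count = snps_within))), n)
    famA <- generate_family(generator_spec(
      seed = sub_seeds[1], signal_variant = "short18",
      motif_counts = c(hexa = 8L, nona = 4L),
      mutations = mk_muts(n_per_cluster), n_genes = n_per_cluster,
      anchors = anchors))
    famB <- generate_family(generator_spec(
      seed = sub_seeds[2], signal_variant = "long21",
      motif_counts = c(hexa = 6L, nona = 6L),
      n_genes = n_per_cluster, anchors = anchors))
    # fixed between-cluster separation: nonsynonymous template edits
    # spread across cluster B's repetitive domain (including the first
    # and last motifs, which enter the analysis regions), applied
    # identically to every member before the private SNPs
    offB <- 3L * 126L
    repB <- 90L
    sep_sites <- c(2L, 5L, 9L, 14L, 19L, 40L, 46L, 72L, 78L, 84L, 88L)
    n_div <- 21L + c(8L, 17L, 30L, 44L, 64L, 75L, 85L, 93L)
    protB <- translate_dna(famB$genes[[1]]$sequence)
    rep_aaB <- substr(protB, 127L, 126L + repB)
    # cluster B's N-terminal domain diverges as a second lineage, so the
    # between-cluster signal dominates the private within-cluster SNPs
    # in the analysis regions (the planted-partition regime)
    diverge_codon <- function(s, p) {
      res <- substr(protB, p, p)
      if (res == "C") return(s)
      codon <- wheat_codon_table()[[divergence_map[[res]]]]
      paste0(substr(s, 1L, 3L * (p - 1L)), codon,
             substr(s, 3L * p + 1L, nchar(s)))
    }
    genesB <- lapply(famB$genes, function(g) {
      s <- g$sequence
      for (p in n_div) s <- diverge_codon(s, p)
      for (a in sep_sites) {
        s <- plant_snp(s, offB, a, substr(rep_aaB, a, a), "nonsyn")
      }
      for (e in random_snp_edits(s, c(offB + 1L, offB + 3L * repB),
                                 snps_within)) {
        s <- apply_substitution(s, e$position, e$alt)
      }
      gene_record(g$id, s, source = "simulate_two_cluster_family")
    })
    famO <- generate_family(generator_spec(
      seed = sub_seeds[3], signal_variant = "long21",
      motif_counts = c(hexa = 5L, nona = 7L),
      mutations = list(list(mutation_spec("snp", count = 25L))),
      n_genes = 1L, anchors = anchors))

    rename <- function(g, id) gene_record(id, g$sequence, source = g$source)
    genes <- c(
      setNames(lapply(seq_len(n_per_cluster), function(i) {
        rename(famA$genes[[i]], paste0("A", i))
      }), paste0("A", seq_len(n_per_cluster))),
      setNames(lapply(seq_len(n_per_cluster), function(i) {
        rename(genesB[[i]], paste0("B", i))
      }), paste0("B", seq_len(n_per_cluster))),
      list(OUT = rename(famO$genes[[1]], "OUT"))
    )
    list(genes = genes,
         clusters = list(A = paste0("A", seq_len(n_per_cluster)),
                         B = paste0("B", seq_len(n_per_cluster))),
         outgroup = "OUT")
  })
}
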