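test_that("identical genes show no variation", {
  fam <- generate_family(generator_spec(seed = 1))
  r <- compare_pair(fam$genes[[1]], fam$genes[[1]])
  expect_equal(r$snp_count, 0L)
  expect_equal(nrow(r$indels), 0L)
})

test_that("planted SNPs and motif-block indels are recovered exactly", {
  fam <- generate_family(generator_spec(
    seed = 13, n_genes = 4L,
    mutations = list(NULL,
                     list(mutation_spec("snp", count = 6L)),
                     list(mutation_spec("motif_block_insertion",
                                        n_motifs = 2L)),
                     list(mutation_spec("motif_block_deletion",
                                        n_motifs = 1L)))))
  r_snp <- compare_pair(fam$genes[[1]], fam$genes[[2]])
  expect_equal(r_snp$snp_count, 6L)
  expect_equal(nrow(r_snp$indels), 0L)

  want_ins <- fam$truth[[3]]$mutations[[1]]$length_nt
  r_ins <- compare_pair(fam$genes[[1]], fam$genes[[3]])
  expect_equal(r_ins$snp_count, 0L)
  expect_equal(r_ins$indels$length_nt, want_ins)
  expect_equal(r_ins$indels$side, "b_has_extra")

  want_del <- fam$truth[[4]]$mutations[[1]]$length_nt
  r_del <- compare_pair(fam$genes[[1]], fam$genes[[4]])
  expect_equal(r_del$indels$length_nt, want_del)
  expect_equal(r_del$indels$side, "a_has_extra")
})

test_that("reports are symmetric under argument swap", {
  fam <- generate_family(generator_spec(
    seed = 17, n_genes = 2L,
    mutations = list(NULL, list(mutation_spec("snp", count = 4L),
                                mutation_spec("motif_block_insertion")))))
  ab <- compare_pair(fam$genes[[1]], fam$genes[[2]])
  ba <- compare_pair(fam$genes[[2]], fam$genes[[1]])
  expect_equal(ab$snp_count, ba$snp_count)
  expect_equal(sort(ab$indels$length_nt), sort(ba$indels$length_nt))
  flip <- c(a_has_extra = "b_has_extra", b_has_extra = "a_has_extra")
  expect_equal(sort(unname(flip[ab$indels$side])), sort(ba$indels$side))
})

test_that("alignment scores equal an exhaustive affine-gap oracle", {
  set.seed(303)
  cfg <- hmwgs_config()
  for (i in 1:100) {
    a <- random_dna(sample(4:12, 1L))
    b <- random_dna(sample(4:12, 1L))
    aln <- hmwgs:::align_nt_pair(a, b, cfg)
    expect_equal(aln$score, gotoh_score(a, b), info = paste(a, b))
  }
})

test_that("pairwise SNP counts obey the triangle inequality", {
  for (seed in 1:20) {
    fam <- generate_family(generator_spec(
      seed = seed, n_genes = 3L,
      mutations = list(NULL,
                       list(mutation_spec("snp", count = 5L)),
                       list(mutation_spec("snp", count = 7L)))))
    r12 <- compare_pair(fam$genes[[1]], fam$genes[[2]])$snp_count
    r13 <- compare_pair(fam$genes[[1]], fam$genes[[3]])$snp_count
    r23 <- compare_pair(fam$genes[[2]], fam$genes[[3]])$snp_count
    expect_lte(r13, r12 + r23)
    expect_lte(r23, r12 + r13)
    expect_lte(r12, r13 + r23)
  }
})

test_that("gap placement is leftmost-normalized and deterministic", {
  # deletion inside a homopolymer run: the reported interval starts at
  # the leftmost equivalent position
  a <- gene_record("a", "ATGCAAAAATGCTAGTGA")
  b <- gene_record("b", "ATGCAAAATGCTAGTGA")   # one A of the run deleted
  r <- compare_pair(a, b)
  expect_equal(r$indels$length_nt, 1L)
  expect_equal(r$indels$side, "a_has_extra")
  expect_equal(r$indels$start, 5L)   # run of A starts at position 5 in a
})

test_that("unrelated sequences are refused", {
  set.seed(9)
  a <- gene_record("a", paste0("ATG", random_dna(300)))
  b <- gene_record("b", paste0("ATG", random_dna(300)))
  expect_error(compare_pair(a, b), "too divergent")
})

test_that("group comparison assigns consistent indel names", {
  fam <- simulate_roegneria_family(seed = 2)
  triad <- fam$genes[c("Rny1", "Rny3", "Ray1")]
  reports <- compare_group(triad)
  tab <- attr(reports, "indel_table")
  expect_equal(tab$name, c("Indel1", "Indel2"))
  expect_equal(tab$length_nt, c(63L, 18L))
  by_pair <- function(x, y) {
    for (r in reports) if (setequal(r$pair, c(x, y))) return(r)
  }
  # the 63-nt indel is Indel1 wherever it appears, the 18-nt Indel2
  expect_setequal(by_pair("Rny1", "Rny3")$indels$name, c("Indel1", "Indel2"))
  expect_equal(by_pair("Rny1", "Ray1")$indels$name, "Indel2")
  expect_equal(by_pair("Rny3", "Ray1")$indels$name, "Indel1")
  expect_error(compare_group(fam$genes[1]), "at least two")
})
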