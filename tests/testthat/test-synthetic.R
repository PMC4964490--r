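test_that("generation is deterministic under a fixed spec and seed", {
  a <- generate_family(generator_spec(seed = 42, n_genes = 2L,
                                      irregular_rate = 0.2))
  b <- generate_family(generator_spec(seed = 42, n_genes = 2L,
                                      irregular_rate = 0.2))
  expect_identical(vapply(a$genes, `[[`, character(1), "sequence"),
                   vapply(b$genes, `[[`, character(1), "sequence"))
  c <- generate_family(generator_spec(seed = 43, n_genes = 2L,
                                      irregular_rate = 0.2))
  expect_false(identical(a$genes[[1]]$sequence, c$genes[[1]]$sequence))
})

test_that("template construction forces the designed domain lengths", {
  fam <- generate_family(generator_spec(seed = 1, signal_variant = "short18",
                                        motif_counts = c(hexa = 20L,
                                                         nona = 10L)))
  tr <- fam$truth[[1]]
  expect_equal(unname(tr$lengths),
               c(18L, 102L, 20L * 6L + 10L * 9L, 42L))
  # intact gene length identity: 3 * (residues + tandem stops)
  expect_equal(tr$length_nt, 3L * (tr$total_len + 2L))
  orf <- find_orf(fam$genes[[1]])
  expect_true(orf$is_intact)
  expect_equal(orf$tandem_stop_count, 2L)
  expect_equal(orf$length_nt, 3L * (nchar(orf$translation) + 2L))
})

test_that("spec validation enforces the linked variants and sane inputs", {
  expect_error(generator_spec(signal_variant = "short18",
                              n_terminal_variant = "aa105"),
               "pairs with")
  expect_error(generator_spec(motif_counts = c(weird = 3L)), "unknown motif")
  expect_error(generator_spec(motif_counts = c(hexa = 0L)), "at least one")
  expect_error(generator_spec(irregular_rate = 1.5), "irregular_rate")
  expect_error(generator_spec(mutations = list(list()), n_genes = 2L),
               "per gene")
  expect_error(mutation_spec("inframe_stop", target_domain = "signal"),
               "repetitive")
  expect_error(mutation_spec("single_base_deletion",
                             target_domain = "repetitive"), "C-terminal")
})

test_that("planted in-frame stops are recovered by ORF analysis", {
  fam <- generate_family(generator_spec(
    seed = 7, n_genes = 2L,
    mutations = list(NULL, list(mutation_spec("inframe_stop", count = 1L)))))
  expect_false(fam$truth[[1]]$is_pseudogene)
  expect_true(fam$truth[[2]]$is_pseudogene)
  orf <- find_orf(fam$genes[[2]])
  expect_length(orf$premature_stops, 1L)
  expect_false(orf$is_intact)
  # the planted ordinal sits inside the repetitive domain
  planted <- fam$truth[[2]]$mutations[[1]]$codon_ordinals
  aa_rng <- fam$truth[[2]]$boundaries_aa["repetitive", ]
  expect_true(planted > aa_rng[1] && planted <= aa_rng[2])
  expect_equal(orf$premature_stops, planted)
})

test_that("twin genes with six planted SNPs differ by exactly six SNPs", {
  fam <- generate_family(generator_spec(
    seed = 9, n_genes = 2L,
    mutations = list(NULL, list(mutation_spec("snp", count = 6L)))))
  rep_ <- compare_pair(fam$genes[[1]], fam$genes[[2]])
  expect_equal(rep_$snp_count, 6L)
  expect_equal(nrow(rep_$indels), 0L)
})

test_that("motif-block indels are whole-motif, 18-63 nt, frame-preserving", {
  for (seed in 1:10) {
    fam <- generate_family(generator_spec(
      seed = seed, n_genes = 2L,
      mutations = list(NULL, list(mutation_spec("motif_block_insertion")))))
    mut <- fam$truth[[2]]$mutations[[1]]
    expect_true(mut$length_nt %% 3L == 0L)
    expect_gte(mut$length_nt, 18L)
    expect_lte(mut$length_nt, 63L)
    rep_ <- compare_pair(fam$genes[[1]], fam$genes[[2]])
    expect_equal(rep_$indels$length_nt, mut$length_nt)
  }
})
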