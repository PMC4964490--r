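test_that("full annotation of mutation-free genes matches ground truth", {
  for (seed in 1:6) {
    fam <- generate_family(varied_spec(seed))
    tr <- fam$truth[[1]]
    ann <- annotate_gene(fam$genes[[1]])
    expect_true(ann$orf$is_intact)
    expect_equal(ann$orf$length_nt, tr$length_nt)
    expect_equal(unname(ann$annotation$boundaries), unname(tr$boundaries_aa))
    expect_equal(ann$decomposition$segments$start, tr$tiling$start)
    expect_equal(ann$decomposition$segments$motif_class,
                 tr$tiling$motif_class)
    expect_equal(ann$translation, tr$protein)
  }
})

test_that("pseudogenes are annotated on the corrected frame", {
  fam <- generate_family(generator_spec(
    seed = 21, n_genes = 2L,
    mutations = list(NULL, list(mutation_spec("inframe_stop", count = 2L),
                                mutation_spec("single_base_deletion")))))
  tr <- fam$truth[[2]]
  ann <- annotate_gene(fam$genes[[2]], reference = fam$genes[[1]])
  expect_false(ann$orf$is_intact)
  expect_length(ann$orf$premature_stops, 2L)
  expect_length(ann$frameshift, 1L)
  expect_true(ann$annotation$reconstructed)
  # the corrected frame restores the designed domain sizes
  expect_equal(ann$annotation$signal_len, unname(tr$lengths["signal"]))
  expect_equal(ann$annotation$repetitive_len,
               unname(tr$lengths["repetitive"]))
  expect_equal(ann$annotation$c_terminal_len,
               unname(tr$lengths["c_terminal"]))
  # without a reference the frameshifted tail cannot be corrected, so
  # the C-terminal anchor fails with a diagnostic
  expect_error(annotate_gene(fam$genes[[2]]), "segmentation error")
  # a stops-only pseudogene needs no reference: the frame is unbroken
  fam2 <- generate_family(generator_spec(
    seed = 22, mutations = list(list(mutation_spec("inframe_stop")))))
  ann0 <- annotate_gene(fam2$genes[[1]])
  expect_false(ann0$orf$is_intact)
  expect_false(isTRUE(ann0$annotation$reconstructed))
  expect_equal(ann0$annotation$repetitive_len,
               unname(fam2$truth[[1]]$lengths["repetitive"]))
})

test_that("the domain table collects one row per gene", {
  fam <- generate_family(generator_spec(seed = 2, n_genes = 2L))
  tab <- domain_table(annotate_family(fam$genes))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$gene, c("g1", "g2"))
  expect_true(all(tab$total_len == tab$signal_len + tab$n_terminal_len +
                    tab$repetitive_len + tab$c_terminal_len))
  expect_true(all(tab$intact))
})

test_that("the CLI subcommands run end to end", {
  pre <- tempfile()
  hmwgs_main(c("simulate", "--seed", "2", "--out", pre, "--n-genes", "2"))
  fa <- paste0(pre, ".fa")
  expect_true(file.exists(fa))
  expect_true(file.exists(paste0(pre, ".truth.json")))

  out_json <- tempfile(fileext = ".json")
  tab <- tempfile(fileext = ".tsv")
  hmwgs_main(c("annotate", "--in", fa, "--out", out_json, "--table", tab))
  ann <- read_annotations(out_json)
  expect_length(ann, 2L)
  expect_true(file.exists(tab))

  cmp <- tempfile(fileext = ".tsv")
  hmwgs_main(c("compare", "--in", fa, "--out", cmp))
  cmp_tab <- read.delim(cmp)
  expect_equal(nrow(cmp_tab), 1L)

  # tree over region FASTA
  fam <- simulate_two_cluster_family(seed = 1, n_per_cluster = 2L)
  bundles <- annotate_family(fam$genes)
  regs <- vapply(bundles, function(b) {
    slice_flanking_regions(b$annotation, b$decomposition, b$translation)$n_region
  }, character(1))
  rf <- tempfile(fileext = ".fa")
  writeLines(paste0(">", names(regs), "\n", regs), rf)
  nw <- tempfile(fileext = ".nwk")
  hmwgs_main(c("tree", "--in", rf, "--out", nw, "--outgroup", "OUT",
               "--bootstrap", "50"))
  tree <- ape::read.tree(nw)
  expect_setequal(tree$tip.label, names(regs))
  expect_error(hmwgs_main(c("nonsense")), "unknown subcommand")
})
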