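test_that("progressive alignment handles identity and planted indels", {
  ident <- align_regions(c(a = "PGQGQQGYY", b = "PGQGQQGYY",
                           c = "PGQGQQGYY"))
  expect_equal(ncol(ident), 9L)
  expect_false(any(ident == "-"))

  base <- strrep("GYYPTSPQQ", 4)
  with_ins <- paste0(substr(base, 1, 18), "PGQGQQ",
                     substr(base, 19, nchar(base)))
  msa <- align_regions(c(a = base, b = with_ins, c = base))
  expect_equal(ncol(msa), nchar(with_ins))
  gap_cols <- which(msa["a", ] == "-")
  expect_length(gap_cols, 6L)
  expect_equal(gap_cols, seq(min(gap_cols), length.out = 6L))  # one block
  expect_equal(msa["c", gap_cols], rep("-", 6L))

  expect_error(align_regions(c(a = "PG", b = "PG")), "at least 3")
  # columns never fewer than the longest input
  set.seed(11)
  regs <- setNames(vapply(1:6, function(i) {
    paste(sample(c("P", "G", "Q", "Y"), sample(10:20, 1), replace = TRUE),
          collapse = "")
  }, character(1)), paste0("s", 1:6))
  msa2 <- align_regions(regs)
  expect_gte(ncol(msa2), max(nchar(regs)))
})

test_that("three-taxon neighbor joining solves the closed form", {
  d <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tree <- nj_from_distances(d)
  lens <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 1, 3))
})

test_that("p and Poisson distances match their closed forms", {
  msa <- rbind(a = strsplit("AAAA", "")[[1]],
               b = strsplit("AAAT", "")[[1]],
               c = strsplit("AAAA", "")[[1]])
  expect_equal(region_distances(msa)["a", "b"], 0.25)
  expect_equal(region_distances(msa, "poisson")["a", "b"], -log(0.75))
  # Poisson >= p for all p in (0, 1)
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(-log(1 - p) >= p))
  # zero shared columns is an error
  msa2 <- rbind(a = c("A", "-", "-"), b = c("-", "A", "A"),
                c = c("A", "A", "A"))
  expect_error(region_distances(msa2), "share no alignment columns")
})

test_that("NJ reconstructs the generating topology from additive distances", {
  set.seed(404)
  for (i in 1:30) {
    tr <- ape::rtree(8)
    d <- ape::cophenetic.phylo(tr)
    perm <- sample(rownames(d))
    nj <- nj_from_distances(d[perm, perm])
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(nj)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("bootstrap supports are invariant to taxon input order", {
  fam <- simulate_roegneria_family(seed = 3)
  bundles <- annotate_family(fam$genes, reference = "Rny1")
  regions <- vapply(bundles, function(b) {
    slice_flanking_regions(b$annotation, b$decomposition, b$translation)$n_region
  }, character(1))
  msa <- align_regions(regions)
  t1 <- build_tree(msa, bootstrap_n = 100L, outgroup = "Dhord", seed = 5)
  perm <- msa[sample(rownames(msa)), , drop = FALSE]
  t2 <- build_tree(perm, bootstrap_n = 100L, outgroup = "Dhord", seed = 5)
  expect_equal(ape::dist.topo(ape::unroot(t1$tree), ape::unroot(t2$tree)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(t1$supports), sort(t2$supports))
})

test_that("group assignment follows the smallest reference clade", {
  # caterpillar with one reference per group and nested queries
  phy <- ape::read.tree(text = "(((q1,ref1),(q2,ref2)),((q3,ref3),out));")
  refs <- c(ref1 = "g1", ref2 = "g2", ref3 = "g3")
  groups <- assign_groups(phy, refs)
  expect_equal(unname(groups[c("q1", "q2", "q3")]), c("g1", "g2", "g3"))
  # mixed-reference clade leaves the query unresolved
  phy2 <- ape::read.tree(text = "((q1,(ref1,ref2)),out);")
  g2 <- assign_groups(phy2, c(ref1 = "a", ref2 = "b"))
  expect_equal(unname(g2["q1"]), "unresolved")
  expect_error(assign_groups(phy, c(nope = "g1")), "missing from the tree")
})

test_that("planted two-cluster families are recovered as two clades", {
  ok <- 0L
  for (seed in 1:10) {
    fam <- simulate_two_cluster_family(seed = seed)
    bundles <- annotate_family(fam$genes)
    regions <- vapply(bundles, function(b) {
      slice_flanking_regions(b$annotation, b$decomposition,
                             b$translation)$n_region
    }, character(1))
    tree <- build_tree(align_regions(regions), bootstrap_n = 0L,
                       outgroup = fam$outgroup)
    ok <- ok + (clade_is_monophyletic(tree, fam$clusters$A) &&
                  clade_is_monophyletic(tree, fam$clusters$B))
  }
  expect_gte(ok, 9L)
})
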