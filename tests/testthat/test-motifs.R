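test_that("worked repeat fragments tile as documented", {
  # pristine dodecapeptide: two hexapeptides
  d <- decompose_repeats("PGQGQQPGQGQQ")
  expect_equal(nrow(d$segments), 2L)
  expect_equal(d$segments$motif_class, c("hexa", "hexa"))
  expect_equal(sum(d$segments$edit_distance), 0L)

  # 21-residue hexa-variant / nona / hexa-variant fragment
  d2 <- decompose_repeats("PEQGQQGYYPTSPQQPGKGQQ")
  expect_equal(nrow(d2$segments), 3L)
  expect_equal(d2$segments$motif_class, c("hexa", "nona", "hexa"))
  expect_equal(sum(d2$segments$end - d2$segments$start), 21L)
  expect_equal(d2$segments$edit_distance, c(1L, 0L, 1L))

  # 9-residue nonapeptide variant
  d3 <- decompose_repeats("QGYYPTSPQ")
  expect_equal(nrow(d3$segments), 1L)
  expect_equal(d3$segments$motif_class, "nona")
  expect_equal(d3$segments$end - d3$segments$start, 9L)

  # irregular motifs keep their own classes
  d4 <- decompose_repeats("PGGQQGYYPTSPHQQ")
  expect_equal(d4$segments$motif_class,
               c("irregular_penta", "irregular_deca"))
  expect_equal(sum(d4$segments$edit_distance), 0L)
})

test_that("decomposition is lossless on arbitrary residue strings", {
  set.seed(101)
  alphabet <- c("P", "G", "Q", "Y", "T", "S", "A", "L", "E", "K", "W")
  for (i in 1:40) {
    n <- sample(1:40, 1L)
    s <- paste(sample(alphabet, n, replace = TRUE), collapse = "")
    d <- decompose_repeats(s)
    expect_identical(paste(d$segments$sequence, collapse = ""), s)
    # contiguity / non-overlap
    expect_equal(d$segments$start,
                 c(0L, head(d$segments$end, -1L)))
    expect_equal(d$segments$end[nrow(d$segments)], nchar(s))
  }
  expect_error(decompose_repeats(""), "empty")
})

test_that("pristine template concatenations tile into exactly k segments", {
  set.seed(55)
  tmpl <- motif_templates()
  for (i in 1:20) {
    k <- sample(2:12, 1L)
    classes <- sample(c("hexa", "nona", "irregular_penta",
                        "irregular_deca"), k, replace = TRUE)
    s <- paste(tmpl[classes], collapse = "")
    d <- decompose_repeats(s)
    expect_equal(nrow(d$segments), k)
    expect_equal(d$segments$motif_class, classes)
    expect_equal(sum(d$segments$edit_distance), 0L)
    expect_equal(d$irregular_fraction,
                 sum(nchar(tmpl[classes[grepl("irregular", classes)]])) /
                   nchar(s))
  }
})

test_that("inserting one template motif raises its class count by one", {
  set.seed(77)
  tmpl <- motif_templates()
  for (i in 1:10) {
    arrangement <- sample(c("hexa", "nona"), 8L, replace = TRUE)
    s <- paste(tmpl[arrangement], collapse = "")
    base <- decompose_repeats(s)
    ins_class <- sample(c("hexa", "nona"), 1L)
    at <- sample(0:8, 1L)
    lens <- cumsum(nchar(tmpl[arrangement]))
    cut <- if (at == 0L) 0L else lens[at]
    s2 <- paste0(substr(s, 1, cut), tmpl[[ins_class]],
                 substr(s, cut + 1L, nchar(s)))
    d2 <- decompose_repeats(s2)
    expect_equal(d2$counts[[ins_class]], base$counts[[ins_class]] + 1L)
  }
})

test_that("the DP matches an exhaustive tiling oracle on short strings", {
  set.seed(202)
  tmpl <- motif_templates()
  cases <- character(0)
  for (i in 1:30) {     # noisy template concatenations, <= 24 aa
    classes <- sample(names(tmpl), sample(2:3, 1L), replace = TRUE)
    s <- paste(tmpl[classes], collapse = "")
    chars <- strsplit(s, "")[[1]]
    nmut <- sample(0:2, 1L)
    if (nmut > 0) {
      at <- sample(seq_along(chars), nmut)
      chars[at] <- sample(c("A", "E", "K", "Q", "G"), nmut, replace = TRUE)
    }
    cases <- c(cases, substr(paste(chars, collapse = ""), 1, 24))
  }
  for (i in 1:20) {     # arbitrary strings
    cases <- c(cases, paste(sample(c("P", "G", "Q", "Y", "T", "S", "A"),
                                   sample(3:24, 1L), replace = TRUE),
                            collapse = ""))
  }
  for (s in cases) {
    expect_equal(decompose_repeats(s)$total_cost, tiling_oracle_cost(s),
                 info = s)
  }
})

test_that("unclassified runs are truly outside every class threshold", {
  thr <- c(tri = 1L, hexa = 2L, nona = 3L, irregular_penta = 2L,
           irregular_deca = 3L)
  check_others <- function(segments) {
    other <- segments[segments$motif_class == "other", , drop = FALSE]
    for (s in other$sequence) {
      d <- vapply(motif_templates(), function(t) {
        as.integer(adist(s, t))
      }, integer(1))
      expect_true(all(d > thr[names(d)]), info = s)
    }
    nrow(other)
  }
  # a foreign stretch between motifs must surface as an "other" run
  d <- decompose_repeats("PGQGQQWWLWMWGYYPTSPQQ")
  expect_gte(check_others(d$segments), 1L)
  # worst case: nothing motif-like at all collapses to one run
  d2 <- decompose_repeats("WWWWWWWW")
  expect_equal(nrow(d2$segments), 1L)
  expect_equal(d2$segments$motif_class, "other")
  expect_equal(d2$irregular_fraction, 1)
  # generator output stays clean
  res <- annotate_structure(generate_family(varied_spec(6))$genes[[1]])
  check_others(res$decomposition$segments)
})

test_that("flanking regions are sliced by segment counts", {
  fam <- generate_family(generator_spec(seed = 8))
  res <- annotate_structure(fam$genes[[1]])
  orf <- res$orf
  regions <- slice_flanking_regions(res$annotation, res$decomposition,
                                    orf$translation)
  segs <- res$decomposition$segments
  expect_equal(nchar(regions$n_region),
               res$annotation$n_terminal_len + segs$end[3])
  expect_equal(nchar(regions$c_region),
               res$annotation$c_terminal_len +
                 segs$end[nrow(segs)] - segs$start[nrow(segs) - 5L])
  # boundary case: exactly six segments consume the whole repeat
  six <- decompose_repeats(strrep("PGQGQQ", 6))
  fake_ann <- res$annotation
  fake_tr <- paste0(substr(orf$translation, 1,
                           fake_ann$boundaries["repetitive", 1]),
                    strrep("PGQGQQ", 6),
                    substr(orf$translation,
                           fake_ann$boundaries["repetitive", 2] + 1L,
                           nchar(orf$translation)))
  fake_ann$boundaries["repetitive", 2] <-
    fake_ann$boundaries["repetitive", 1] + 36L
  fake_ann$boundaries["c_terminal", ] <-
    c(fake_ann$boundaries["repetitive", 2],
      fake_ann$boundaries["repetitive", 2] + fake_ann$c_terminal_len)
  fake_ann$total_len <- nchar(fake_tr)
  r6 <- slice_flanking_regions(fake_ann, six, fake_tr)
  expect_equal(nchar(r6$c_region), 36L + fake_ann$c_terminal_len)
  # fewer than six segments is an explicit error
  two <- decompose_repeats("PGQGQQPGQGQQ")
  expect_error(slice_flanking_regions(fake_ann, two, fake_tr),
               "slice_last_motifs")
})
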