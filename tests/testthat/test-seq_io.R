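test_that("FASTA records parse minimally, in order, uppercased", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">g1 first gene", "atgtaa", ">g2", "ATGAAATAGTGA"), fa)
  recs <- read_gene_sequences(fa)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "g1")
  expect_equal(recs[[1]]$sequence, "ATGTAA")
  expect_equal(recs[[1]]$description, "first gene")
  expect_equal(recs[[2]]$sequence, "ATGAAATAGTGA")
})

test_that("sequence validation reports the record and offset", {
  expect_error(gene_record("bad", "ATGRAA"), "'bad'.*offset 4")
  expect_error(gene_record("e", ""), "empty")
  # ambiguity codes pass only with the override flag
  rec <- gene_record("amb", "ATGNAA", allow_ambiguity = TRUE)
  expect_true(rec$has_ambiguity)
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ATG", ">a", "ATG"), fa)
  expect_error(read_gene_sequences(fa), "duplicate")
  expect_error(read_gene_sequences(tempfile(fileext = ".fa")), "no such file")
  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_gene_sequences(empty), "no records")
})

test_that("GenBank flat files parse, single and multi record", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       REC1                    12 bp    DNA     linear   PLN 01-JAN-2020",
    "DEFINITION  synthetic test record one.",
    "ACCESSION   REC1",
    "ORIGIN",
    "        1 atgaaatagt ga",
    "//",
    "LOCUS       REC2                     6 bp    DNA     linear   PLN 01-JAN-2020",
    "ACCESSION   REC2",
    "ORIGIN",
    "        1 atgtaa",
    "//"), gb)
  recs <- read_gene_sequences(gb)   # format guessed from extension
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "REC1")
  expect_equal(recs[[1]]$sequence, "ATGAAATAGTGA")
  expect_match(recs[[1]]$description, "synthetic")
  expect_equal(recs[[2]]$sequence, "ATGTAA")
  expect_error(read_gene_sequences(gb, "fasta"))
})

test_that("FASTA written by the package round-trips identically", {
  fam <- generate_family(generator_spec(seed = 11, n_genes = 3L))
  fa <- tempfile(fileext = ".fa")
  write_gene_sequences(fam$genes, fa)
  back <- read_gene_sequences(fa)
  expect_equal(vapply(back, `[[`, character(1), "id"),
               vapply(fam$genes, `[[`, character(1), "id"))
  expect_equal(vapply(back, `[[`, character(1), "sequence"),
               vapply(fam$genes, `[[`, character(1), "sequence"))
})

test_that("JSON annotations round-trip all domain lengths exactly", {
  fam <- generate_family(generator_spec(seed = 5))
  ann <- annotate_gene(fam$genes[[1]])
  path <- tempfile(fileext = ".json")
  write_annotations(list(ann), path, "json")
  back <- read_annotations(path)[["g1"]]
  expect_equal(back$domains$signal_len, ann$annotation$signal_len)
  expect_equal(back$domains$n_terminal_len, ann$annotation$n_terminal_len)
  expect_equal(back$domains$repetitive_len, ann$annotation$repetitive_len)
  expect_equal(back$domains$c_terminal_len, ann$annotation$c_terminal_len)
  expect_equal(back$orf$length_nt, ann$orf$length_nt)
  expect_equal(length(back$motifs$segments), nrow(ann$decomposition$segments))
})

test_that("GFF3 domain features partition the translated span", {
  fam <- generate_family(generator_spec(seed = 5))
  ann <- annotate_gene(fam$genes[[1]])
  path <- tempfile(fileext = ".gff3")
  write_annotations(list(ann), path, "gff3")
  gr <- rtracklayer::import(path)
  doms <- gr[gr$type %in% c("signal_peptide", "n_terminal", "repetitive",
                            "c_terminal")]
  doms <- doms[order(IRanges::start(doms))]
  expect_length(doms, 4L)
  starts <- IRanges::start(doms); ends <- IRanges::end(doms)
  expect_equal(starts[1], 1L)
  expect_equal(starts[-1], head(ends, -1) + 1L)   # contiguous, non-overlap
  expect_equal(ends[4], 3L * ann$annotation$total_len)
  segs <- gr[gr$type == "motif_segment"]
  expect_equal(length(segs), nrow(ann$decomposition$segments))
})

test_that("writing an empty bundle list is an error, not an empty file", {
  path <- tempfile(fileext = ".json")
  expect_error(write_annotations(list(), path), "empty")
  expect_false(file.exists(path))
})
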