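# Shared helpers for the test suite.

# fast structural annotation (segmentation + decomposition + census)
# without the classification / frameshift stages, for property loops
annotate_structure <- function(gene, config = hmwgs_config()) {
  orf <- find_orf(gene)
  ann <- segment_domains(orf, config = config)
  b <- ann$boundaries
  repetitive <- substr(orf$translation, b["repetitive", 1] + 1L,
                       b["repetitive", 2])
  dec <- decompose_repeats(repetitive, config, gene_id = gene$id)
  census <- cysteine_census(ann, orf$translation, config)
  list(orf = orf, annotation = ann, decomposition = dec, census = census)
}

# a seed-indexed generator spec that varies the template shape
varied_spec <- function(seed, mutations = list(), n_genes = 1L) {
  variant <- if (seed %% 2L == 0L) "long21" else "short18"
  counts <- switch((seed %% 3L) + 1L,
    c(hexa = 20L, nona = 10L),
    c(hexa = 12L, nona = 8L, penta = 2L),
    c(hexa = 15L, nona = 6L, deca = 1L, penta = 1L))
  generator_spec(seed = seed, signal_variant = variant,
                 motif_counts = counts,
                 irregular_rate = 0,
                 mutations = mutations, n_genes = n_genes)
}

# independent affine-gap global alignment score (Gotoh), following the
# same convention as the implementation: a gap run of length L costs
# gap_open + L * gap_ext, end gaps included
gotoh_score <- function(a, b, match = 2, mismatch = -1,
                        gap_open = 6, gap_ext = 0.5) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (consumes x)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (consumes y)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(gap_open + (i - 1) * gap_ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(gap_open + (j - 1) * gap_ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                     X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# independent memoized minimum-cost tiling over all segmentations,
# same cost model as decompose_repeats (top-down, no tie-breaking)
tiling_oracle_cost <- function(s, config = hmwgs_config()) {
  templates <- motif_templates()
  thr <- c(tri = 1L, hexa = 2L, nona = 3L, irregular_penta = 2L,
           irregular_deca = 3L)
  bias <- setNames(rep(0, length(templates)), names(templates))
  bias["tri"] <- config$motif_tri_bias
  n <- nchar(s)
  memo <- rep(NA_real_, n + 1L)
  solve <- function(i) {   # min cost of tiling s[1..i]
    if (i == 0L) return(0)
    if (!is.na(memo[i + 1L])) return(memo[i + 1L])
    best <- solve(i - 1L) + config$motif_other_penalty
    for (cl in names(templates)) {
      tl <- nchar(templates[[cl]])
      for (len in max(1L, tl - thr[[cl]]):(tl + thr[[cl]])) {
        if (len > i) next
        e <- as.integer(adist(substr(s, i - len + 1L, i), templates[[cl]]))
        if (e <= thr[[cl]]) {
          best <- min(best, solve(i - len) + e + bias[[cl]])
        }
      }
    }
    memo[i + 1L] <<- best
    best
  }
  solve(n)
}
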