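# Deterministic progressive multiple alignment of the (short) analysis
# regions. The guide order comes from single-linkage clustering of
# pairwise percent identity; profiles are merged by profile-profile
# dynamic programming (sum-of-pairs column scores, linear gap penalty,
# fixed tie-break order), so the result is identical across runs and
# platforms.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

profile_freqs <- function(mat) {
  # mat: character matrix (rows = sequences); returns frequency array
  # (alphabet+gap) x columns
  alph <- c(AA_ALPHABET, "-")
  apply(mat, 2, function(col) {
    tabulate(match(col, alph), nbins = length(alph))
  })
}

profile_pair_scores <- function(fa, fb, match, mismatch) {
  n_alph <- length(AA_ALPHABET)
  ra <- fa[seq_len(n_alph), , drop = FALSE]
  rb <- fb[seq_len(n_alph), , drop = FALSE]
  nonA <- colSums(ra); gapA <- fa[n_alph + 1L, ]
  nonB <- colSums(rb); gapB <- fb[n_alph + 1L, ]
  match_sum <- crossprod(ra, rb)                   # residue agreement
  pairs_res <- outer(nonA, nonB)
  mism <- pairs_res - match_sum
  chargap <- outer(gapA, nonB) + outer(nonA, gapB)
  rowsA <- nonA[1] + gapA[1]; rowsB <- nonB[1] + gapB[1]
  (match * match_sum + mismatch * mism + mismatch * chargap) /
    (rowsA * rowsB)
}

merge_profiles <- function(ma, mb, config) {
  fa <- profile_freqs(ma); fb <- profile_freqs(mb)
  S <- profile_pair_scores(fa, fb, config$aa_match, config$aa_mismatch)
  path <- .profile_align_path(S, config$msa_gap_open, config$msa_gap_ext)
  ncol_out <- length(path$a)
  out <- matrix("-", nrow(ma) + nrow(mb), ncol_out)
  rownames(out) <- c(rownames(ma), rownames(mb))
  out[seq_len(nrow(ma)), path$a != 0L] <- ma[, path$a[path$a != 0L],
                                             drop = FALSE]
  out[nrow(ma) + seq_len(nrow(mb)), path$b != 0L] <- mb[, path$b[path$b != 0L],
                                                        drop = FALSE]
  out
}

#' Progressive multiple alignment of region sequences
#'
#' @param regions named character vector (or named list) of >= 3 residue
#'   strings.
#' @param config a [hmwgs_config()].
#' @return A character matrix of aligned single characters, rows named
#'   by input names and returned in input order; `"-"` denotes a gap.
#' @export
align_regions <- function(regions, config = hmwgs_config()) {
  regions <- unlist(regions)
  if (length(regions) < 3L) stop("need at least 3 sequences to align")
  if (is.null(names(regions)) || anyDuplicated(names(regions))) {
    stop("regions must have unique names")
  }
  ids <- names(regions)
  n <- length(regions)
  # guide: single linkage on pairwise identity distance
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- align_aa_pair(regions[[i]], regions[[j]], config)
      d[i, j] <- d[j, i] <- 1 - aln$identity
    }
  }
  hc <- hclust(as.dist(d), method = "single")
  profiles <- lapply(regions, function(s) {
    m <- matrix(strsplit(s, "")[[1]], nrow = 1L)
    m
  })
  for (i in seq_len(n)) rownames(profiles[[i]]) <- ids[i]
  merged <- vector("list", n - 1L)
  for (k in seq_len(nrow(hc$merge))) {
    pick <- function(x) if (x < 0) profiles[[-x]] else merged[[x]]
    merged[[k]] <- merge_profiles(pick(hc$merge[k, 1]),
                                  pick(hc$merge[k, 2]), config)
  }
  res <- merged[[n - 1L]]
  res[ids, , drop = FALSE]
}

msa_as_strings <- function(msa) {
  apply(msa, 1, paste, collapse = "")
}
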