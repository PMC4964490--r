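# Pairwise variation accounting between orthologous genes: SNP columns,
# indels (maximal gap runs, leftmost-normalized), and the amino-acid
# layer restricted to the repetitive domain.
#
# Conventions: a SNP is an aligned column holding two different bases;
# columns inside gap runs are never SNP columns. Terminal stop codons
# are part of the aligned region. At the amino-acid layer, substitution
# columns count only residue-vs-residue differences: columns containing
# a gap, an internal stop (*) or an undetermined residue (X) are
# excluded and reported indel peptides come from maximal gap runs.

#' Compare two orthologous genes
#'
#' Globally aligns the two nucleotide sequences (affine gaps, leftmost
#' gap normalization) and reports SNP and indel variation. When both
#' genes can be annotated -- or annotation bundles are supplied, e.g.
#' frame-corrected pseudogene bundles from [annotate_gene()] -- the
#' amino-acid layer of the repetitive domain is reported as well.
#'
#' @param a,b `gene_record`s.
#' @param config a [hmwgs_config()].
#' @param bundle_a,bundle_b optional `hmwgs_annotation` bundles for the
#'   two genes, used for the repetitive-domain amino-acid layer.
#' @return An object of class `variation_report`: `pair`, `snp_count`,
#'   `snps` (positions on both sequences plus the two bases), `indels`
#'   (maximal gap runs: `length_nt`, `side` = which gene has the extra
#'   bases, 1-based interval on that gene, extra sequence),
#'   `aa_substitutions_repetitive` (NA when no amino-acid layer is
#'   available) and `aa_fragment_indels`.
#' @examples
#' fam <- simulate_roegneria_family(seed = 1)
#' rep_ <- compare_pair(fam$genes$Rny1, fam$genes$Rny3)
#' rep_$snp_count
#' @export
compare_pair <- function(a, b, config = hmwgs_config(),
                         bundle_a = NULL, bundle_b = NULL) {
  stopifnot(inherits(a, "gene_record"), inherits(b, "gene_record"))
  aln <- align_nt_pair(a$sequence, b$sequence, config)
  if (aln$identity < config$divergence_floor) {
    stop("sequences too divergent (", sprintf("%.2f", aln$identity),
         " identity over aligned bases, floor ",
         config$divergence_floor, ")")
  }
  ac <- aln$a_chars; bc <- aln$b_chars
  both <- ac != "-" & bc != "-"
  snp_cols <- which(both & ac != bc)
  a_pos <- cumsum(ac != "-")
  b_pos <- cumsum(bc != "-")
  snps <- data.frame(pos_a = a_pos[snp_cols], pos_b = b_pos[snp_cols],
                     base_a = ac[snp_cols], base_b = bc[snp_cols],
                     stringsAsFactors = FALSE)

  gaps_in_b <- gap_runs(bc, ac)   # a has extra bases
  gaps_in_a <- gap_runs(ac, bc)   # b has extra bases
  indels <- rbind(
    if (nrow(gaps_in_b)) data.frame(side = "a_has_extra", gaps_in_b),
    if (nrow(gaps_in_a)) data.frame(side = "b_has_extra", gaps_in_a)
  )
  if (is.null(indels)) {
    indels <- data.frame(side = character(0), col_start = integer(0),
                         col_end = integer(0), length_nt = integer(0),
                         start = integer(0), end = integer(0),
                         sequence = character(0))
  }
  indels <- indels[order(-indels$length_nt, indels$col_start), ,
                   drop = FALSE]
  rownames(indels) <- NULL
  indels$name <- if (nrow(indels)) paste0("Indel", seq_len(nrow(indels)))
                 else character(0)

  aa <- compare_repetitive_aa(bundle_a, bundle_b, config)

  structure(
    list(pair = c(a$id, b$id),
         snp_count = nrow(snps),
         snps = snps,
         indels = indels[, c("name", "side", "length_nt", "start", "end",
                             "sequence", "col_start", "col_end")],
         aa_substitutions_repetitive = aa$substitutions,
         aa_fragment_indels = aa$fragment_indels,
         alignment_identity = aln$identity,
         alignment_score = aln$score),
    class = "variation_report"
  )
}

compare_repetitive_aa <- function(bundle_a, bundle_b, config) {
  empty <- list(substitutions = NA_integer_,
                fragment_indels = data.frame(length_aa = integer(0),
                                             peptide = character(0)))
  if (is.null(bundle_a) || is.null(bundle_b)) return(empty)
  rep_of <- function(bundle) {
    bnd <- bundle$annotation$boundaries
    substr(bundle$translation, bnd["repetitive", 1] + 1L,
           bnd["repetitive", 2])
  }
  ra <- rep_of(bundle_a); rb <- rep_of(bundle_b)
  aln <- align_aa_pair(ra, rb, config)
  ac <- aln$a_chars; bc <- aln$b_chars
  residues <- ac != "-" & bc != "-" & ac != "*" & bc != "*" &
    ac != "X" & bc != "X"
  subs <- sum(residues & ac != bc)
  runs <- rbind(gap_runs(ac, bc), gap_runs(bc, ac))
  fragment_indels <- data.frame(
    length_aa = runs$length_nt,
    peptide = runs$sequence,
    stringsAsFactors = FALSE
  )
  fragment_indels <- fragment_indels[order(-fragment_indels$length_aa), ,
                                     drop = FALSE]
  rownames(fragment_indels) <- NULL
  list(substitutions = as.integer(subs), fragment_indels = fragment_indels)
}

#' @export
print.variation_report <- function(x, ...) {
  cat(sprintf("<variation_report> %s vs %s: %d SNP(s), %d indel(s)\n",
              x$pair[1], x$pair[2], x$snp_count, nrow(x$indels)))
  if (nrow(x$indels)) {
    for (i in seq_len(nrow(x$indels))) {
      cat(sprintf("  %s: %d nt (%s, %d-%d)\n", x$indels$name[i],
                  x$indels$length_nt[i], x$indels$side[i],
                  x$indels$start[i], x$indels$end[i]))
    }
  }
  if (!is.na(x$aa_substitutions_repetitive)) {
    cat(sprintf("  repetitive-domain aa substitutions: %d\n",
                x$aa_substitutions_repetitive))
  }
  invisible(x)
}

#' Compare all pairs in a gene group
#'
#' Runs [compare_pair()] on every unordered pair and assigns stable
#' indel names across the group: indels are matched across pairs by
#' their length and extra-side sequence, then named `Indel1`, `Indel2`,
#' ... by descending length and, at equal length, by coordinate of first
#' appearance, so the same physical indel carries the same name in every
#' report it appears in.
#'
#' @param genes list of >= 2 `gene_record`s.
#' @param config a [hmwgs_config()].
#' @param bundles optional named list of `hmwgs_annotation` bundles
#'   (names = gene ids) enabling the amino-acid layer.
#' @return A list of `variation_report`s with consistent indel names;
#'   attribute `"indel_table"` maps each name to its length.
#' @export
compare_group <- function(genes, config = hmwgs_config(), bundles = NULL) {
  if (length(genes) < 2L) stop("need at least two genes to compare")
  ids <- vapply(genes, `[[`, character(1), "id")
  pairs <- utils::combn(length(genes), 2L)
  reports <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    compare_pair(genes[[i]], genes[[j]], config,
                 bundle_a = bundles[[ids[i]]], bundle_b = bundles[[ids[j]]])
  })
  # collect distinct indels over the group
  keys <- character(0); lens <- integer(0); first_coord <- integer(0)
  for (r in reports) {
    for (i in seq_len(nrow(r$indels))) {
      key <- paste0(r$indels$length_nt[i], ":", r$indels$sequence[i])
      if (!key %in% keys) {
        keys <- c(keys, key)
        lens <- c(lens, r$indels$length_nt[i])
        first_coord <- c(first_coord, r$indels$start[i])
      }
    }
  }
  if (length(keys)) {
    ord <- order(-lens, first_coord)
    name_map <- setNames(paste0("Indel", seq_along(keys)), keys[ord])
    reports <- lapply(reports, function(r) {
      if (nrow(r$indels)) {
        key <- paste0(r$indels$length_nt, ":", r$indels$sequence)
        r$indels$name <- unname(name_map[key])
      }
      r
    })
    attr(reports, "indel_table") <-
      data.frame(name = paste0("Indel", seq_along(keys)),
                 length_nt = lens[ord], stringsAsFactors = FALSE)
  } else {
    attr(reports, "indel_table") <-
      data.frame(name = character(0), length_nt = integer(0))
  }
  reports
}
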