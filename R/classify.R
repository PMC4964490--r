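# x-type / y-type diagnostic classification.
#
# The two subunit classes encoded at a Glu-1 locus differ in a small set
# of discrete features. Seven diagnostics are evaluated, each pointing
# towards x or y, and combined by an equal-weight vote:
#   1. N-terminal domain length: 102/105 aa is y-like (x-types are
#      shorter, ~80-90 aa).
#   2. Five N-terminal cysteines: y-like (other counts x-like).
#   3. Terminal hexapeptide closing the N-terminal domain: SSQTVQ
#      (y-specific) or SSQPVQ (St-genome variant) are y-like.
#   4. Extra glutamine at the marked N-terminal alignment column:
#      x-like when present.
#   5. Undecapeptide LAAQLPAMCRL in the C-terminal: x-like when present.
#   6. No cysteine near the repetitive-domain C-terminus: x-like.
#   7. Standalone GQQ tripeptide tiles in the repeat: x-like when present.
# Unanimous votes give "x" or "y"; a mixed vote gives an intermediate
# call inclining towards the majority side; a tie is "unclassified".

#' Vote rule over a seven-feature direction vector
#'
#' @param directions character vector of `"x"`, `"y"` or `"neither"`.
#' @return One of `"x"`, `"y"`, `"intermediate_x"`, `"intermediate_y"`,
#'   `"unclassified"`.
#' @export
type_vote <- function(directions) {
  nx <- sum(directions == "x")
  ny <- sum(directions == "y")
  if (nx == 0L && ny == 0L) return("unclassified")
  if (nx == 0L) return("y")
  if (ny == 0L) return("x")
  if (ny > nx) return("intermediate_y")
  if (nx > ny) return("intermediate_x")
  "unclassified"
}

# locate the residue aligned to the template's extra-glutamine column
extra_q_present <- function(n_domain, anchors, config) {
  tmpl <- anchors$n_terminal$aa105
  aln <- align_aa_pair(n_domain, tmpl$sequence, config)
  tpos <- cumsum(aln$b_chars != "-")
  col <- which(tpos == tmpl$extra_q & aln$b_chars != "-")[1]
  if (is.na(col)) return(FALSE)
  aln$a_chars[col] == "Q"
}

#' Classify a subunit as x-type, y-type or intermediate
#'
#' @param annotation a `subunit_annotation`.
#' @param decomposition a `motif_decomposition` of the same gene.
#' @param translation the subunit translation the annotation refers to.
#' @param anchors an `anchor_set`.
#' @param config a [hmwgs_config()].
#' @return An object of class `type_call`: `label` plus an `evidence`
#'   data.frame (`feature`, `observed`, `points_toward`). The label is a
#'   pure function of the seven feature directions via [type_vote()].
#' @export
classify_subunit_type <- function(annotation, decomposition, translation,
                                  anchors = default_anchors(),
                                  config = hmwgs_config()) {
  if (!is.na(annotation$gene_id) && !is.na(decomposition$gene_id) &&
      annotation$gene_id != decomposition$gene_id) {
    stop("annotation and decomposition refer to different genes")
  }
  b <- annotation$boundaries
  n_domain <- substr(translation, b["n_terminal", 1] + 1L, b["n_terminal", 2])
  c_domain <- substr(translation, b["c_terminal", 1] + 1L, b["c_terminal", 2])

  n_len <- annotation$n_terminal_len
  f1 <- if (n_len %in% c(102L, 105L)) "y" else
    if (n_len >= 80L && n_len <= 95L) "x" else "neither"

  n_cys <- length(annotation$cys_positions$signal) +
    length(annotation$cys_positions$n_terminal)
  f2 <- if (n_cys == 5L) "y" else "x"

  hexas <- substr(n_domain, nchar(n_domain) - 5L, nchar(n_domain))
  f3 <- if (grepl("^SSQ[PT]VQ$", hexas)) "y" else "x"

  has_q <- extra_q_present(n_domain, anchors, config)
  f4 <- if (has_q) "x" else "y"

  # single substitutions tolerated in the undecapeptide
  k <- nchar(anchors$undecapeptide)
  idx <- seq_len(max(0L, nchar(c_domain) - k + 1L))
  undeca <- length(idx) > 0L &&
    min(as.integer(adist(substring(c_domain, idx, idx + k - 1L),
                         anchors$undecapeptide))) <= 1L
  f5 <- if (undeca) "x" else "y"

  census <- cysteine_census(annotation, translation, config)
  f6 <- if (census$repeat_terminal_cys) "y" else "x"

  tri_tiles <- decomposition$counts[["tri"]]
  f7 <- if (!is.na(tri_tiles) && tri_tiles > 0L) "x" else "y"

  evidence <- data.frame(
    feature = c("n_terminal_length", "n_terminal_cys_count",
                "terminal_hexapeptide", "extra_glutamine",
                "c_terminal_undecapeptide", "repeat_terminal_cys",
                "tripeptide_tiles"),
    observed = c(as.character(n_len), as.character(n_cys), hexas,
                 as.character(has_q), as.character(undeca),
                 as.character(census$repeat_terminal_cys),
                 as.character(tri_tiles)),
    points_toward = c(f1, f2, f3, f4, f5, f6, f7),
    stringsAsFactors = FALSE
  )
  structure(
    list(gene_id = annotation$gene_id,
         label = type_vote(evidence$points_toward),
         evidence = evidence),
    class = "type_call"
  )
}

#' @export
print.type_call <- function(x, ...) {
  cat(sprintf("<type_call>%s %s\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              x$label))
  for (i in seq_len(nrow(x$evidence))) {
    cat(sprintf("  %-26s %-8s -> %s\n", x$evidence$feature[i],
                x$evidence$observed[i], x$evidence$points_toward[i]))
  }
  invisible(x)
}
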