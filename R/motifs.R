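# Motif-grammar decomposition of the central repetitive domain.
#
# The repetitive core of an HMW-GS is a tandem array built from a small
# peptide vocabulary: the tripeptide GQQ, the hexapeptide PGQGQQ, the
# nonapeptide GYYPTSPQQ, and their irregular variants, the pentapeptide
# PGGQQ and the decapeptide GYYPTSPHQQ. Observed copies are frequently
# single- or double-substitution "mutants" of the canonical motifs, so
# segments are classified by edit distance rather than exact match.

#' Motif template library
#'
#' @return Named character vector of canonical and irregular motif
#'   templates, names being the motif classes.
#' @export
motif_templates <- function() {
  c(tri = "GQQ",
    hexa = "PGQGQQ",
    nona = "GYYPTSPQQ",
    irregular_penta = "PGGQQ",
    irregular_deca = "GYYPTSPHQQ")
}

# maximum edit distance at which a segment still belongs to a class
motif_class_thresholds <- function() {
  c(tri = 1L, hexa = 2L, nona = 3L, irregular_penta = 2L,
    irregular_deca = 3L)
}

#' Decompose a repetitive domain into classified motif segments
#'
#' Dynamic-programming segmentation of the residue string into an
#' ordered, lossless tiling. The objective minimizes the total edit
#' distance of the segments to their motif templates, with a per-residue
#' penalty (`motif_other_penalty`) for residues left in unclassified
#' "other" runs and a small surcharge (`motif_tri_bias`) on standalone
#' GQQ tiles so that hexa/nona tilings win ties. Remaining ties are
#' broken by fewest segments, then by preferring the longer motif.
#'
#' Candidate segment lengths for a template of length L with class
#' threshold t are L-t .. L+t; a segment is assigned a class only when
#' its edit distance is within the class threshold (1 for tri, 2 for
#' hexa/penta, 3 for nona/deca). The concatenation of the segment
#' sequences always equals the input exactly.
#'
#' @param repetitive residue string (non-empty).
#' @param config a [hmwgs_config()].
#' @param gene_id optional identifier carried into the result.
#' @return An object of class `motif_decomposition` with `segments`
#'   (data.frame: `start`/`end` 0-based half-open, `motif_class`,
#'   `sequence`, `edit_distance`), per-class `counts`, and
#'   `irregular_fraction` (fraction of residues in irregular or
#'   unclassified segments).
#' @examples
#' decompose_repeats("PGQGQQPGQGQQ")$segments
#' @export
decompose_repeats <- function(repetitive, config = hmwgs_config(),
                              gene_id = NA_character_) {
  stopifnot(is.character(repetitive), length(repetitive) == 1L)
  n <- nchar(repetitive)
  if (n == 0L) stop("repetitive domain is empty")
  templates <- motif_templates()
  thr <- motif_class_thresholds()
  p_other <- config$motif_other_penalty
  bias <- setNames(rep(0, length(templates)), names(templates))
  bias["tri"] <- config$motif_tri_bias

  # precompute edit distances of every candidate segment to each template
  # d_list[[class]][[as.character(len)]][i] = dist of segment ending at i
  cand <- list()
  for (cl in names(templates)) {
    tl <- nchar(templates[[cl]])
    for (len in max(1L, tl - thr[[cl]]):(tl + thr[[cl]])) {
      if (len > n) next
      idx_end <- len:n
      segs <- substring(repetitive, idx_end - len + 1L, idx_end)
      d <- as.integer(adist(segs, templates[[cl]]))
      keep <- d <= thr[[cl]]
      if (any(keep)) {
        cand[[length(cand) + 1L]] <- list(
          class = cl, len = len,
          end = idx_end[keep], dist = d[keep],
          cost = d[keep] + bias[[cl]]
        )
      }
    }
  }
  # order candidates longest-motif-first for deterministic tie-breaks
  if (length(cand)) {
    ord <- order(-vapply(cand, function(x) nchar(templates[[x$class]]),
                         numeric(1)),
                 -vapply(cand, `[[`, numeric(1), "len"))
    cand <- cand[ord]
  }
  # flatten to per-end-position candidate table
  by_end <- vector("list", n)
  for (cc in cand) {
    for (k in seq_along(cc$end)) {
      i <- cc$end[k]
      by_end[[i]] <- c(by_end[[i]], list(list(
        class = cc$class, len = cc$len, dist = cc$dist[k], cost = cc$cost[k]
      )))
    }
  }

  INF <- Inf
  cost <- c(0, rep(INF, n))
  nseg <- c(0L, rep(NA_integer_, n))
  prev <- rep(NA_integer_, n + 1L)
  cls <- rep(NA_character_, n + 1L)
  seg_dist <- rep(NA_integer_, n + 1L)
  seg_len_at <- rep(NA_integer_, n + 1L)
  eps <- 1e-9
  for (i in seq_len(n)) {
    ii <- i + 1L
    # unclassified residue: extend or open an "other" run
    prev_other <- !is.na(cls[ii - 1L]) && cls[ii - 1L] == "other"
    cost[ii] <- cost[ii - 1L] + p_other
    nseg[ii] <- nseg[ii - 1L] + if (prev_other) 0L else 1L
    prev[ii] <- i - 1L
    cls[ii] <- "other"
    seg_dist[ii] <- NA_integer_
    seg_len_at[ii] <- 1L
    for (cc in by_end[[i]]) {
      j <- i - cc$len
      if (cost[j + 1L] >= INF) next
      new_cost <- cost[j + 1L] + cc$cost
      new_nseg <- nseg[j + 1L] + 1L
      better <- new_cost < cost[ii] - eps ||
        (abs(new_cost - cost[ii]) <= eps &&
           (new_nseg < nseg[ii] ||
              (new_nseg == nseg[ii] && cc$len > seg_len_at[ii])))
      if (better) {
        cost[ii] <- new_cost
        nseg[ii] <- new_nseg
        prev[ii] <- j
        cls[ii] <- cc$class
        seg_dist[ii] <- cc$dist
        seg_len_at[ii] <- cc$len
      }
    }
  }

  # traceback
  ends <- integer(0); starts <- integer(0); classes <- character(0)
  dists <- integer(0)
  i <- n
  while (i > 0L) {
    j <- prev[i + 1L]
    ends <- c(i, ends); starts <- c(j, starts)
    classes <- c(cls[i + 1L], classes)
    dists <- c(seg_dist[i + 1L], dists)
    i <- j
  }
  segs <- data.frame(start = starts, end = ends, motif_class = classes,
                     edit_distance = dists, stringsAsFactors = FALSE)
  # merge adjacent single-residue "other" steps into maximal runs
  if (nrow(segs) > 1L) {
    out <- segs[1, , drop = FALSE]
    for (k in 2:nrow(segs)) {
      at <- nrow(out)
      if (segs$motif_class[k] == "other" && out$motif_class[at] == "other") {
        out$end[at] <- segs$end[k]
      } else {
        out <- rbind(out, segs[k, , drop = FALSE])
      }
    }
    segs <- out
    rownames(segs) <- NULL
  }
  segs$sequence <- substring(repetitive, segs$start + 1L, segs$end)
  segs <- segs[, c("start", "end", "motif_class", "sequence", "edit_distance")]

  counts <- table(factor(segs$motif_class,
                         levels = c(names(templates), "other")))
  irregular_res <- sum(segs$end[segs$motif_class %in%
                                  c("irregular_penta", "irregular_deca", "other")] -
                       segs$start[segs$motif_class %in%
                                    c("irregular_penta", "irregular_deca", "other")])
  structure(
    list(gene_id = gene_id, segments = segs,
         counts = as.integer(counts) |> setNames(names(counts)),
         total_cost = cost[n + 1L],
         irregular_fraction = irregular_res / n),
    class = "motif_decomposition"
  )
}

#' @export
print.motif_decomposition <- function(x, ...) {
  cat(sprintf("<motif_decomposition>%s %d segments over %d aa\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              nrow(x$segments), sum(x$segments$end - x$segments$start)))
  cnt <- x$counts[x$counts > 0]
  cat("  ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "),
      sprintf("(irregular fraction %.3f)\n", x$irregular_fraction))
  invisible(x)
}

#' Extract the two flanking analysis regions for phylogeny
#'
#' The N-side region is the signal-stripped N-terminal domain plus the
#' first `slice_first_motifs` (default 3) repetitive segments; the C-side
#' region is the last `slice_last_motifs` (default 6) segments plus the
#' C-terminal domain. The "motif" unit is the decomposition segment,
#' irregular segments included.
#'
#' @param annotation a `subunit_annotation` (see [segment_domains()]).
#' @param decomposition a `motif_decomposition` of the same gene.
#' @param translation the full subunit translation the annotation refers to.
#' @param config a [hmwgs_config()].
#' @return `list(n_region =, c_region =)` of residue strings.
#' @export
slice_flanking_regions <- function(annotation, decomposition, translation,
                                   config = hmwgs_config()) {
  n_first <- config$slice_first_motifs
  n_last <- config$slice_last_motifs
  segs <- decomposition$segments
  if (nrow(segs) < n_last) {
    stop("decomposition has only ", nrow(segs), " segments; fewer than ",
         n_last, " -- reduce slice_last_motifs in hmwgs_config()")
  }
  b <- annotation$boundaries
  n_dom <- substr(translation, b["n_terminal", 1] + 1L, b["n_terminal", 2])
  rep_off <- b["repetitive", 1]
  first_end <- segs$end[min(n_first, nrow(segs))]
  n_region <- paste0(n_dom,
                     substr(translation, rep_off + 1L, rep_off + first_end))
  last_start <- segs$start[nrow(segs) - n_last + 1L]
  c_dom <- substr(translation, b["c_terminal", 1] + 1L, b["c_terminal", 2])
  c_region <- paste0(substr(translation, rep_off + last_start + 1L,
                            rep_off + segs$end[nrow(segs)]),
                     c_dom)
  list(n_region = n_region, c_region = c_region)
}
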