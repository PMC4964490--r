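# Distance-based phylogeny of the two analysis regions: p- or
# Poisson-corrected distances with pairwise gap deletion, neighbor
# joining, nonparametric bootstrap over alignment columns, and
# clade-based group assignment against reference subunits.

#' Pairwise distances from an alignment matrix
#'
#' Distances are computed over the columns where both sequences have a
#' residue (pairwise deletion, so the long gap blocks created by
#' repeat-number variation do not discard whole columns for every
#' pair). `p_distance` is the proportion of differing shared columns;
#' `poisson` applies the multiple-hit correction -ln(1 - p).
#'
#' @param msa character matrix from [align_regions()].
#' @param model `"p_distance"` or `"poisson"`.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
region_distances <- function(msa, model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  n <- nrow(msa)
  ids <- rownames(msa)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- msa[i, ] != "-" & msa[j, ] != "-"
      if (!any(shared)) {
        stop("taxa '", ids[i], "' and '", ids[j],
             "' share no alignment columns")
      }
      p <- mean(msa[i, shared] != msa[j, shared])
      if (model == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p >= 1 (pair ",
                         ids[i], ", ", ids[j], ")")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor joining with optional outgroup rooting
#'
#' Thin wrapper around [ape::nj()] that validates the matrix and roots
#' the result on the outgroup.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @param outgroup optional taxon id to root on.
#' @return An `ape::phylo` tree.
#' @export
nj_from_distances <- function(d, outgroup = NULL) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d),
            isTRUE(all.equal(d, t(d), tolerance = 1e-8)),
            all(is.finite(d)))
  tree <- ape::nj(as.dist(d))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) {
      stop("outgroup '", outgroup, "' is not among the taxa")
    }
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  tree
}

#' Build a bootstrap-supported neighbor-joining tree from an alignment
#'
#' Distances under the chosen model feed neighbor joining; support
#' values come from a nonparametric bootstrap over alignment columns
#' (columns resampled with replacement under a fixed seed) and are
#' expressed as the percentage of replicates containing each internal
#' split. Support values are attached as node labels of the returned
#' tree (empty at the root).
#'
#' @param msa character matrix from [align_regions()].
#' @param model distance model, see [region_distances()].
#' @param bootstrap_n number of bootstrap pseudoreplicates (>= 0).
#' @param outgroup taxon id used to root the tree.
#' @param seed RNG seed for the bootstrap resampling.
#' @param config a [hmwgs_config()].
#' @return An object of class `hmwgs_tree`: the rooted `phylo` tree with
#'   supports as node labels, the Newick string, and the run metadata
#'   (`model`, `bootstrap_n`, `seed`, `outgroup`).
#' @export
build_tree <- function(msa, model = c("p_distance", "poisson"),
                       bootstrap_n = 500L, outgroup = NULL, seed = 1L,
                       config = hmwgs_config()) {
  model <- match.arg(model)
  stopifnot(bootstrap_n >= 0L)
  # canonical taxon order: supports and topology do not depend on the
  # order sequences were supplied in
  msa <- msa[order(rownames(msa)), , drop = FALSE]
  d <- region_distances(msa, model)
  main <- nj_from_distances(d, outgroup)
  supports <- NULL
  if (bootstrap_n > 0L) {
    reps <- with_seed(seed, function() {
      lapply(seq_len(bootstrap_n), function(b) {
        repeat {
          cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
          db <- try(region_distances(msa[, cols, drop = FALSE], model),
                    silent = TRUE)
          if (!inherits(db, "try-error")) {
            return(ape::nj(as.dist(db)))
          }
        }
      })
    })
    counts <- ape::prop.clades(main, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0L
    supports <- round(100 * counts / bootstrap_n, 1)
    main$node.label <- as.character(supports)
    if (!is.null(outgroup)) main$node.label[1] <- ""
  }
  structure(
    list(tree = main,
         newick = ape::write.tree(main),
         supports = supports,
         model = model, bootstrap_n = bootstrap_n,
         outgroup = outgroup, seed = seed),
    class = "hmwgs_tree"
  )
}

#' @export
print.hmwgs_tree <- function(x, ...) {
  cat(sprintf("<hmwgs_tree> %d taxa, %s distances, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$model, x$bootstrap_n))
  cat("  ", x$newick, "\n")
  invisible(x)
}

#' @export
plot.hmwgs_tree <- function(x, show.node.label = TRUE, ...) {
  ape::plot.phylo(x$tree, show.node.label = show.node.label, ...)
  invisible(x)
}

tip_sets_of_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  sets <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # edges in postorder so children are resolved before parents
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    sets[[parent]] <- c(sets[[parent]], sets[[child]])
  }
  sets
}

#' Assign taxa to groups by their enclosing reference clade
#'
#' Each unlabeled taxon inherits the group of the smallest clade that
#' contains it together with at least one reference taxon, provided all
#' references inside that clade belong to a single group; otherwise the
#' taxon is `"unresolved"`. The outgroup (when recorded in the tree) is
#' labeled `"outgroup"`.
#'
#' @param tree an `hmwgs_tree` or `ape::phylo`.
#' @param references named character vector: reference taxon -> group.
#' @return Named character vector over all tips.
#' @export
assign_groups <- function(tree, references) {
  phy <- if (inherits(tree, "hmwgs_tree")) tree$tree else tree
  outgroup <- if (inherits(tree, "hmwgs_tree")) tree$outgroup else NULL
  if (!all(names(references) %in% phy$tip.label)) {
    stop("reference taxa missing from the tree: ",
         paste(setdiff(names(references), phy$tip.label), collapse = ", "))
  }
  sets <- tip_sets_of_nodes(phy)
  n_tip <- length(phy$tip.label)
  parent_of <- function(node) {
    hit <- phy$edge[phy$edge[, 2] == node, 1]
    if (length(hit)) hit else NA_integer_
  }
  out <- setNames(rep(NA_character_, n_tip), phy$tip.label)
  for (i in seq_len(n_tip)) {
    tip <- phy$tip.label[i]
    if (!is.null(outgroup) && tip == outgroup) {
      out[tip] <- "outgroup"
      next
    }
    if (tip %in% names(references)) {
      out[tip] <- references[[tip]]
      next
    }
    node <- parent_of(i)
    assigned <- "unresolved"
    while (!is.na(node)) {
      refs_in <- intersect(sets[[node]], names(references))
      if (length(refs_in)) {
        groups <- unique(references[refs_in])
        assigned <- if (length(groups) == 1L) groups else "unresolved"
        break
      }
      node <- parent_of(node)
    }
    out[tip] <- assigned
  }
  out
}

#' Is a set of tips monophyletic (given a rooted tree)?
#'
#' @param tree an `hmwgs_tree` or `phylo`.
#' @param tips character vector of tip labels.
#' @return `TRUE` when some clade contains exactly these tips.
#' @export
clade_is_monophyletic <- function(tree, tips) {
  phy <- if (inherits(tree, "hmwgs_tree")) tree$tree else tree
  sets <- tip_sets_of_nodes(phy)
  any(vapply(sets, function(s) setequal(s, tips), logical(1)))
}
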