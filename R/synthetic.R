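# Synthetic HMW-GS gene generator.
#
# Genes are assembled from the anchor templates (signal peptide,
# N-terminal, C-terminal) and a motif arrangement for the repetitive
# domain, reverse-translated with a fixed codon per residue so that
# output is deterministic, and terminated by two tandem stop codons
# (TGA TAG). Mutations are planted with exact recorded coordinates, so
# downstream stages can be tested against known ground truth.

# one fixed codon per residue (frequent wheat codons); determinism matters
# more than codon-usage realism here
wheat_codon_table <- function() {
  c(A = "GCC", R = "AGG", N = "AAC", D = "GAC", C = "TGC", Q = "CAA",
    E = "GAG", G = "GGC", H = "CAC", I = "ATC", L = "CTC", K = "AAG",
    M = "ATG", F = "TTC", P = "CCA", S = "TCC", T = "ACC", W = "TGG",
    Y = "TAC", V = "GTC")
}

reverse_translate <- function(protein) {
  tab <- wheat_codon_table()
  cods <- tab[strsplit(protein, "")[[1]]]
  if (anyNA(cods)) stop("cannot reverse-translate residue(s): ",
                        paste(unique(strsplit(protein, "")[[1]][is.na(cods)]),
                              collapse = ""))
  paste(cods, collapse = "")
}

with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  fn()
}

#' Specify a planted mutation
#'
#' @param kind one of `"snp"`, `"motif_block_insertion"`,
#'   `"motif_block_deletion"`, `"inframe_stop"`, `"single_base_deletion"`.
#' @param count how many events to plant (snp / inframe_stop).
#' @param target_domain domain the mutation is restricted to. In-frame
#'   stops are restricted to the repetitive domain and single-base
#'   deletions to the C-terminal domain, mirroring where such lesions
#'   occur in the gene family's pseudogenes.
#' @param n_motifs for motif-block indels: how many whole motifs to
#'   insert or delete (1-3; drawn at random when `NULL`). Whole-motif
#'   blocks give the 18-63 nt, frame-preserving indel sizes seen between
#'   orthologues.
#' @param positions optional explicit 1-based nt positions (snp,
#'   single_base_deletion) or codon ordinals (inframe_stop).
#' @return A `mutation_spec` object.
#' @export
mutation_spec <- function(kind = c("snp", "motif_block_insertion",
                                   "motif_block_deletion", "inframe_stop",
                                   "single_base_deletion"),
                          count = 1L, target_domain = NULL, n_motifs = NULL,
                          positions = NULL) {
  kind <- match.arg(kind)
  default_domain <- switch(kind,
    snp = "repetitive", motif_block_insertion = "repetitive",
    motif_block_deletion = "repetitive", inframe_stop = "repetitive",
    single_base_deletion = "c_terminal")
  if (is.null(target_domain)) target_domain <- default_domain
  if (kind == "inframe_stop" && target_domain != "repetitive") {
    stop("inframe_stop mutations are restricted to the repetitive domain")
  }
  if (kind == "single_base_deletion" && target_domain != "c_terminal") {
    stop("single_base_deletion mutations are restricted to the C-terminal domain")
  }
  if (kind %in% c("motif_block_insertion", "motif_block_deletion") &&
      target_domain != "repetitive") {
    stop("motif-block indels are restricted to the repetitive domain")
  }
  structure(list(kind = kind, count = as.integer(count),
                 target_domain = target_domain, n_motifs = n_motifs,
                 positions = positions),
            class = "mutation_spec")
}

#' Specify a synthetic gene family
#'
#' @param seed RNG seed; identical specs and seeds give byte-identical
#'   output.
#' @param signal_variant `"short18"` or `"long21"`. The 18-aa signal
#'   peptide pairs with the 102-aa N-terminal and the 21-aa signal with
#'   the 105-aa N-terminal: the two lineages differ by one hexapeptide
#'   deletion crossing the signal/N-terminal boundary, so the pairing is
#'   enforced.
#' @param n_terminal_variant `"aa102"` or `"aa105"`; defaults to the
#'   variant linked to `signal_variant`.
#' @param motif_counts named integer vector over the motif classes of
#'   [motif_templates()] (names `tri`, `hexa`, `nona`, `irregular_penta`
#'   / `penta`, `irregular_deca` / `deca`); must yield at least one
#'   motif.
#' @param irregular_rate probability that a hexapeptide is emitted as
#'   the irregular pentapeptide PGGQQ and a nonapeptide as the irregular
#'   decapeptide GYYPTSPHQQ.
#' @param mutations list of per-gene mutation lists: element `i` is a
#'   list of [mutation_spec()]s applied to gene `i` (or `NULL`).
#' @param n_genes number of genes to emit from the same template.
#' @param anchors an `anchor_set`.
#' @return A `generator_spec` object.
#' @export
generator_spec <- function(seed = 1L,
                           signal_variant = c("short18", "long21"),
                           n_terminal_variant = NULL,
                           motif_counts = c(hexa = 20L, nona = 10L),
                           irregular_rate = 0,
                           mutations = list(),
                           n_genes = 1L,
                           anchors = default_anchors()) {
  signal_variant <- match.arg(signal_variant)
  linked <- c(short18 = "aa102", long21 = "aa105")[[signal_variant]]
  if (is.null(n_terminal_variant)) n_terminal_variant <- linked
  if (n_terminal_variant != linked) {
    stop("signal_variant '", signal_variant, "' pairs with n_terminal_variant '",
         linked, "' (the hexapeptide deletion crosses the boundary)")
  }
  names(motif_counts) <- sub("^penta$", "irregular_penta",
                             sub("^deca$", "irregular_deca",
                                 names(motif_counts)))
  bad <- setdiff(names(motif_counts), names(motif_templates()))
  if (length(bad)) stop("unknown motif class(es): ", paste(bad, collapse = ", "))
  if (sum(motif_counts) < 1L) {
    stop("motif_counts must yield a repetitive domain of at least one motif")
  }
  if (irregular_rate < 0 || irregular_rate > 1) {
    stop("irregular_rate must be in [0, 1]")
  }
  if (length(mutations) && length(mutations) != n_genes) {
    stop("mutations must have one element (possibly NULL) per gene")
  }
  structure(list(seed = as.integer(seed), signal_variant = signal_variant,
                 n_terminal_variant = n_terminal_variant,
                 motif_counts = motif_counts,
                 irregular_rate = irregular_rate, mutations = mutations,
                 n_genes = as.integer(n_genes), anchors = anchors),
            class = "generator_spec")
}

# arrangement -> repetitive residue string
repeat_from_arrangement <- function(arrangement) {
  paste(motif_templates()[arrangement], collapse = "")
}

# tiling data.frame (0-based half-open, repeat coordinates)
tiling_from_arrangement <- function(arrangement) {
  tmpl <- motif_templates()
  lens <- nchar(tmpl[arrangement])
  ends <- cumsum(lens)
  data.frame(start = ends - lens, end = ends,
             motif_class = unname(arrangement),
             sequence = unname(tmpl[arrangement]),
             edit_distance = 0L, stringsAsFactors = FALSE)
}

# leftmost score-equivalent placement of a single-base deletion at p
leftmost_deletion_pos <- function(sequence, p) {
  ch <- substr(sequence, p, p)
  u <- p
  while (u > 1L && substr(sequence, u - 1L, u - 1L) == ch) u <- u - 1L
  u
}

build_template_gene <- function(spec) {
  anchors <- spec$anchors
  sig <- if (spec$signal_variant == "short18") anchors$signal$short18 else
    anchors$signal$long21
  nterm <- if (spec$n_terminal_variant == "aa102") {
    anchors$n_terminal$aa102$sequence
  } else {
    anchors$n_terminal$aa105$sequence
  }
  counts <- spec$motif_counts
  arrangement <- rep(names(counts), times = counts)
  if (length(arrangement) > 1L) arrangement <- sample(arrangement)
  if (spec$irregular_rate > 0) {
    flip <- stats::runif(length(arrangement)) < spec$irregular_rate
    arrangement[flip & arrangement == "hexa"] <- "irregular_penta"
    arrangement[flip & arrangement == "nona"] <- "irregular_deca"
  }
  list(signal = sig, n_terminal = nterm,
       arrangement = arrangement, c_terminal = anchors$c_terminal)
}

assemble_gene <- function(parts) {
  protein <- paste0(parts$signal, parts$n_terminal,
                    repeat_from_arrangement(parts$arrangement),
                    parts$c_terminal)
  list(protein = protein,
       sequence = paste0(reverse_translate(protein), "TGATAG"))
}

domain_truth <- function(parts) {
  lens <- c(signal = nchar(parts$signal),
            n_terminal = nchar(parts$n_terminal),
            repetitive = sum(nchar(motif_templates()[parts$arrangement])),
            c_terminal = nchar(parts$c_terminal))
  ends <- cumsum(lens)
  b <- cbind(start = ends - lens, end = ends)
  rownames(b) <- names(lens)
  list(lengths = lens, boundaries_aa = b, boundaries_nt = 3L * b,
       total_len = sum(lens))
}

random_snp_edits <- function(sequence, range_nt, count, forbid = integer(0)) {
  # plant `count` substitutions inside range_nt (1-based inclusive nt
  # bounds) without creating an in-frame (ATG-frame) stop codon
  picked <- integer(0)
  edits <- list()
  pool <- setdiff(seq(range_nt[1], range_nt[2]), forbid)
  guard <- 0L
  work <- sequence   # edits accumulate so codon checks see prior edits
  while (length(edits) < count) {
    guard <- guard + 1L
    if (guard > 1000L) stop("could not place the requested SNPs")
    p <- sample(pool, 1L)
    if (p %in% picked) next
    ref <- substr(work, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    cod_start <- 3L * ((p - 1L) %/% 3L) + 1L
    cod <- substr(work, cod_start, cod_start + 2L)
    substr(cod, p - cod_start + 1L, p - cod_start + 1L) <- alt
    if (cod %in% STOP_CODONS) next
    work <- apply_substitution(work, p, alt)
    picked <- c(picked, p)
    edits[[length(edits) + 1L]] <- list(position = p, ref = ref, alt = alt)
  }
  edits
}

apply_substitution <- function(sequence, p, alt) {
  paste0(substr(sequence, 1L, p - 1L), alt,
         substr(sequence, p + 1L, nchar(sequence)))
}

#' Generate a synthetic HMW-GS gene family with ground truth
#'
#' All genes share one template (signal peptide, N-terminal, motif
#' arrangement, C-terminal) and differ only by their planted mutations.
#' Unmutated genes are valid ORFs terminated by two tandem stop codons
#' (TGA TAG), so an intact gene of R residues is exactly 3(R + 2) nt
#' long.
#'
#' @param spec a [generator_spec()].
#' @return `list(genes =, truth =)`: `genes` is a list of `gene_record`s
#'   (`ids `g1`, `g2`, ...), `truth` a parallel list of ground-truth
#'   records holding the domain boundaries (aa and nt, 0-based
#'   half-open), the motif tiling, the exact coordinates of every
#'   planted mutation, and the `is_pseudogene` flag.
#' @examples
#' fam <- generate_family(generator_spec(seed = 1))
#' fam$truth[[1]]$lengths
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, function() {
    parts0 <- build_template_gene(spec)
    genes <- vector("list", spec$n_genes)
    truth <- vector("list", spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      parts <- parts0
      muts <- if (length(spec$mutations) >= g) spec$mutations[[g]] else NULL
      applied <- list()

      # 1. motif-block indels operate on the arrangement
      for (m in muts %||% list()) {
        if (m$kind == "motif_block_insertion") {
          k <- m$n_motifs %||% sample(1:3, 1L)
          repeat {   # whole-motif blocks span 18-63 nt
            ins <- sample(c("hexa", "nona"), k, replace = TRUE)
            if (3L * sum(nchar(motif_templates()[ins])) <= 63L) break
          }
          at <- sample(0:length(parts$arrangement), 1L)
          parts$arrangement <- append(parts$arrangement, ins, after = at)
          dt <- domain_truth(parts)
          off <- dt$boundaries_nt["repetitive", 1]
          seg_nt_end <- off + 3L * sum(nchar(motif_templates()[
            parts$arrangement[seq_len(at)]]))
          applied[[length(applied) + 1L]] <- list(
            kind = m$kind, classes = ins,
            length_nt = 3L * sum(nchar(motif_templates()[ins])),
            after_nt = seg_nt_end)
        } else if (m$kind == "motif_block_deletion") {
          k <- m$n_motifs %||% sample(1:3, 1L)
          k <- min(k, length(parts$arrangement) - 1L)
          at <- sample(seq_len(length(parts$arrangement) - k + 1L), 1L)
          removed <- parts$arrangement[at:(at + k - 1L)]
          parts$arrangement <- parts$arrangement[-(at:(at + k - 1L))]
          applied[[length(applied) + 1L]] <- list(
            kind = m$kind, classes = removed,
            length_nt = 3L * sum(nchar(motif_templates()[removed])))
        }
      }

      dt <- domain_truth(parts)
      built <- assemble_gene(parts)
      s <- built$sequence

      # 2. point substitutions
      for (m in muts %||% list()) {
        if (m$kind == "snp") {
          rng <- dt$boundaries_nt[m$target_domain, ] + c(1L, 0L)
          edits <- if (!is.null(m$positions)) {
            lapply(m$positions, function(p) {
              list(position = p, ref = substr(s, p, p),
                   alt = sample(setdiff(c("A", "C", "G", "T"),
                                        substr(s, p, p)), 1L))
            })
          } else {
            random_snp_edits(s, rng, m$count)
          }
          for (e in edits) s <- apply_substitution(s, e$position, e$alt)
          applied[[length(applied) + 1L]] <- c(list(kind = "snp"),
                                               list(edits = edits))
        } else if (m$kind == "inframe_stop") {
          aa_rng <- dt$boundaries_aa["repetitive", ]
          ords <- if (!is.null(m$positions)) m$positions else
            sample((aa_rng[1] + 2L):(aa_rng[2] - 1L), m$count)
          for (a in ords) {
            cod_start <- 3L * (a - 1L) + 1L
            s <- paste0(substr(s, 1L, cod_start - 1L), "TGA",
                        substr(s, cod_start + 3L, nchar(s)))
          }
          applied[[length(applied) + 1L]] <- list(kind = "inframe_stop",
                                                  codon_ordinals = ords)
        }
      }

      # 3. single-base deletion last (shifts downstream coordinates)
      for (m in muts %||% list()) {
        if (m$kind == "single_base_deletion") {
          rng <- dt$boundaries_nt["c_terminal", ]
          p <- if (!is.null(m$positions)) m$positions[1] else
            sample((rng[1] + 1L):(rng[2] - 3L), 1L)
          expected <- leftmost_deletion_pos(s, p)
          s <- paste0(substr(s, 1L, p - 1L), substr(s, p + 1L, nchar(s)))
          applied[[length(applied) + 1L]] <- list(
            kind = "single_base_deletion", position = p,
            expected_event_position = expected)
        }
      }

      kinds <- vapply(applied, `[[`, character(1), "kind")
      genes[[g]] <- gene_record(paste0("g", g), s, source = "generate_family")
      truth[[g]] <- structure(
        list(gene_id = paste0("g", g),
             lengths = dt$lengths,
             boundaries_aa = dt$boundaries_aa,
             boundaries_nt = dt$boundaries_nt,
             total_len = dt$total_len,
             length_nt = nchar(s),
             tiling = tiling_from_arrangement(parts$arrangement),
             protein = built$protein,
             mutations = applied,
             is_pseudogene = any(kinds %in% c("inframe_stop",
                                              "single_base_deletion"))),
        class = "gene_ground_truth")
    }
    list(genes = genes, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
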