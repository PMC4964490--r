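# Whole-gene annotation: ORF analysis, conceptual translation for
# pseudogenes, domain segmentation, motif decomposition and type call,
# gathered into one bundle per gene.

#' Annotate a single HMW-GS gene
#'
#' Runs the full structural pipeline. For genes whose ORF is not intact,
#' the analysis runs on the conceptual translation: premature stop
#' codons are carried through as `*`, and -- when an intact `reference`
#' gene is supplied -- single-base-deletion frameshifts are detected and
#' corrected by reinserting one `N` at each deletion site (the affected
#' codon translates to `X`), with the annotation flagged
#' `reconstructed`. This mirrors how domain sizes of pseudogenes are
#' conventionally reported from their inferred ancestral frame.
#'
#' @param gene a `gene_record`.
#' @param anchors an `anchor_set`.
#' @param config a [hmwgs_config()].
#' @param reference optional intact `gene_record` used to localize
#'   frameshifts in non-intact genes.
#' @return An object of class `hmwgs_annotation`: `gene_id`, `orf`
#'   (`orf_record`), `frameshift` (list of `frameshift_event`s),
#'   `translation` (the translation actually annotated), `annotation`
#'   (`subunit_annotation`), `decomposition` (`motif_decomposition`),
#'   `cysteines` (census) and `type_call`.
#' @examples
#' fam <- generate_family(generator_spec(seed = 1))
#' ann <- annotate_gene(fam$genes[[1]])
#' ann$annotation$repetitive_len
#' @export
annotate_gene <- function(gene, anchors = default_anchors(),
                          config = hmwgs_config(), reference = NULL) {
  orf <- find_orf(gene)
  events <- list()
  reconstructed <- FALSE
  if (orf$is_intact) {
    translation <- orf$translation
  } else {
    seq_use <- gene$sequence
    if (!is.null(reference)) {
      events <- detect_frameshift(gene, reference, config)
      if (length(events)) {
        seq_use <- reconstruct_frame(gene, events)$sequence
        reconstructed <- TRUE
      }
    }
    full <- translate_dna(substr(seq_use, orf$orf_start + 1L,
                                 nchar(seq_use)))
    translation <- sub("\\*+$", "", full)
  }
  annotation <- segment_domains(orf, anchors, config,
                                translation = translation,
                                reconstructed = reconstructed)
  b <- annotation$boundaries
  repetitive <- substr(translation, b["repetitive", 1] + 1L,
                       b["repetitive", 2])
  decomposition <- decompose_repeats(repetitive, config,
                                     gene_id = gene$id)
  census <- cysteine_census(annotation, translation, config)
  type_call <- classify_subunit_type(annotation, decomposition,
                                     translation, anchors, config)
  structure(
    list(gene_id = gene$id, orf = orf, frameshift = events,
         translation = translation, annotation = annotation,
         decomposition = decomposition, cysteines = census,
         type_call = type_call),
    class = "hmwgs_annotation"
  )
}

#' @export
print.hmwgs_annotation <- function(x, ...) {
  cat(sprintf("<hmwgs_annotation> %s\n", x$gene_id))
  print(x$orf)
  if (length(x$frameshift)) {
    for (e in x$frameshift) print(e)
  }
  print(x$annotation)
  print(x$decomposition)
  print(x$type_call)
  invisible(x)
}

#' Annotate a gene collection
#'
#' @param genes list of `gene_record`s.
#' @param anchors an `anchor_set`.
#' @param config a [hmwgs_config()].
#' @param reference optional intact `gene_record` (or the id of a member
#'   of `genes`) used for frameshift correction of non-intact genes.
#' @return Named list of `hmwgs_annotation` bundles.
#' @export
annotate_family <- function(genes, anchors = default_anchors(),
                            config = hmwgs_config(), reference = NULL) {
  ids <- vapply(genes, `[[`, character(1), "id")
  if (is.character(reference) && length(reference) == 1L &&
      reference %in% ids) {
    reference <- genes[[match(reference, ids)]]
  }
  setNames(lapply(genes, annotate_gene, anchors = anchors,
                  config = config, reference = reference), ids)
}

#' Table-style domain summary of annotated genes
#'
#' One row per gene with the ORF size and the per-domain residue and
#' cysteine counts, in the layout conventional for HMW-GS gene tables.
#'
#' @param bundles list of `hmwgs_annotation` objects.
#' @return A data.frame.
#' @export
domain_table <- function(bundles) {
  if (inherits(bundles, "hmwgs_annotation")) bundles <- list(bundles)
  rows <- lapply(bundles, function(b) {
    a <- b$annotation
    cys <- lengths(a$cys_positions)
    data.frame(
      gene = b$gene_id,
      orf_bp = b$orf$length_nt,
      signal_len = a$signal_len,
      n_terminal_len = a$n_terminal_len,
      n_terminal_cys = unname(cys["signal"] + cys["n_terminal"]),
      repetitive_len = a$repetitive_len,
      repetitive_cys = unname(cys["repetitive"]),
      c_terminal_len = a$c_terminal_len,
      c_terminal_cys = unname(cys["c_terminal"]),
      total_len = a$total_len,
      total_cys = unname(sum(cys)),
      intact = b$orf$is_intact,
      premature_stops = length(b$orf$premature_stops),
      type = b$type_call$label,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
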