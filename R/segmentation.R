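# Four-domain segmentation of the translated subunit:
# signal peptide | N-terminal | central repetitive | C-terminal.
#
# Boundaries are located from the family's conserved anchors rather than
# by de novo prediction: the signal/N boundary from the best-matching
# signal-peptide template, the N/repetitive boundary from the terminal
# hexapeptide SSQ[PT]VQ that closes the N-terminal domain, and the
# repetitive/C boundary from the suffix that best matches the C-terminal
# consensus (which carries the undecapeptide LAAQLPAMCRL). Anchor
# matching is alignment-based with a fixed substitution score, so single
# substitutions inside an anchor do not break segmentation.

score_aa_global <- function(a, b, config) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = sub_matrix_for(a, b, config$aa_match,
                                        config$aa_mismatch),
    gapOpening = config$gap_opening, gapExtension = config$gap_extension
  )
  Biostrings::score(pa)
}

locate_signal_boundary <- function(translation, anchors, config) {
  head_aa <- substr(translation, 1L, 30L)
  best <- NULL
  for (variant in names(anchors$signal)) {
    tmpl <- anchors$signal[[variant]]
    pa <- Biostrings::pairwiseAlignment(
      tmpl, head_aa, type = "global-local",
      substitutionMatrix = sub_matrix_for(tmpl, head_aa, config$aa_match,
                                          config$aa_mismatch),
      gapOpening = config$gap_opening, gapExtension = config$gap_extension
    )
    sc <- Biostrings::score(pa)
    if (is.null(best) || sc > best$score) {
      best <- list(variant = variant, score = sc,
                   end = IRanges::end(Biostrings::subject(pa)),
                   max_score = config$aa_match * nchar(tmpl))
    }
  }
  ok <- best$score >= config$signal_min_identity * best$max_score
  list(signal_len = as.integer(best$end), variant = best$variant,
       atypical = !ok || !(best$end %in% c(18L, 21L)))
}

locate_terminal_hexapeptide <- function(translation, signal_len, anchors) {
  body <- substr(translation, signal_len + 1L, nchar(translation))
  m <- regexpr(anchors$terminal_hexapeptide, body)
  if (m > 0L) {
    return(signal_len + as.integer(m) + 5L)  # last residue of the match
  }
  # fuzzy fallback: first 6-mer within edit distance 1 of either variant
  n <- nchar(body)
  if (n >= 6L) {
    idx <- seq_len(n - 5L)
    sixmers <- substring(body, idx, idx + 5L)
    d <- pmin(as.integer(adist(sixmers, "SSQPVQ")),
              as.integer(adist(sixmers, "SSQTVQ")))
    hit <- which(d <= 1L)
    if (length(hit)) {
      return(signal_len + hit[1] + 5L)
    }
  }
  stop("segmentation error: terminal hexapeptide SSQ[PT]VQ not found ",
       "(closest 6-mer is more than one substitution away); ",
       "the N/repetitive boundary cannot be anchored")
}

locate_cterm_boundary <- function(translation, n_end, anchors, config) {
  total <- nchar(translation)
  tmpl <- anchors$c_terminal
  lengths <- seq(max(25L, nchar(tmpl) - 12L),
                 min(nchar(tmpl) + 12L, total - n_end - 1L))
  if (!length(lengths)) {
    stop("segmentation error: no room for a C-terminal domain")
  }
  scores <- vapply(lengths, function(L) {
    score_aa_global(tmpl, substr(translation, total - L + 1L, total), config)
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] < config$cterm_min_identity * config$aa_match * nchar(tmpl)) {
    stop("segmentation error: C-terminal template alignment score ",
         sprintf("%.1f", scores[best]), " below threshold")
  }
  lengths[best]
}

#' Segment a translated subunit into its four domains
#'
#' @param orf an `orf_record` from [find_orf()], or any object with a
#'   `translation` field; alternatively pass `translation` directly.
#' @param anchors an `anchor_set` ([default_anchors()]).
#' @param config a [hmwgs_config()].
#' @param translation optional residue string overriding
#'   `orf$translation` (used for the conceptual translation of
#'   frame-corrected pseudogenes; internal stop codons may be present as
#'   `*` and are tolerated inside the repetitive domain).
#' @param reconstructed flag recorded in the result when the translation
#'   is a frame-corrected reconstruction.
#' @return An object of class `subunit_annotation`: per-domain residue
#'   lengths, a 4 x 2 matrix `boundaries` of 0-based half-open amino-acid
#'   intervals (rows `signal`, `n_terminal`, `repetitive`, `c_terminal`),
#'   per-domain cysteine positions, `total_len`, and flags
#'   `atypical_signal` and `reconstructed`. For intact subunits the four
#'   intervals partition `[0, total_len)`.
#' @examples
#' fam <- generate_family(generator_spec(seed = 1))
#' orf <- find_orf(fam$genes[[1]])
#' segment_domains(orf)
#' @export
segment_domains <- function(orf, anchors = default_anchors(),
                            config = hmwgs_config(), translation = NULL,
                            reconstructed = FALSE) {
  if (is.null(translation)) {
    stopifnot(!is.null(orf$translation))
    translation <- orf$translation
  }
  if (!nzchar(translation)) stop("empty translation")
  gene_id <- if (!is.null(orf$gene_id)) orf$gene_id else NA_character_
  total <- nchar(translation)

  sig <- locate_signal_boundary(translation, anchors, config)
  n_end <- locate_terminal_hexapeptide(translation, sig$signal_len, anchors)
  c_len <- locate_cterm_boundary(translation, n_end, anchors, config)

  b <- matrix(c(0L, sig$signal_len,
                sig$signal_len, n_end,
                n_end, total - c_len,
                total - c_len, total),
              ncol = 2L, byrow = TRUE,
              dimnames = list(c("signal", "n_terminal", "repetitive",
                                "c_terminal"), c("start", "end")))
  if (b["repetitive", 2] <= b["repetitive", 1]) {
    stop("segmentation error: repetitive domain would be empty")
  }
  chars <- strsplit(translation, "")[[1]]
  cys_positions <- lapply(rownames(b), function(d) {
    which(chars == "C" & seq_along(chars) > b[d, 1] &
            seq_along(chars) <= b[d, 2])
  })
  names(cys_positions) <- rownames(b)

  structure(
    list(gene_id = gene_id,
         signal_len = sig$signal_len,
         n_terminal_len = n_end - sig$signal_len,
         repetitive_len = b["repetitive", 2] - b["repetitive", 1],
         c_terminal_len = c_len,
         total_len = total,
         boundaries = b,
         cys_positions = cys_positions,
         signal_variant = sig$variant,
         atypical_signal = sig$atypical,
         reconstructed = reconstructed),
    class = "subunit_annotation"
  )
}

#' @export
print.subunit_annotation <- function(x, ...) {
  cat(sprintf(
    "<subunit_annotation>%s signal %d | N %d | repetitive %d | C %d = %d aa%s\n",
    if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
    x$signal_len, x$n_terminal_len, x$repetitive_len, x$c_terminal_len,
    x$total_len,
    if (isTRUE(x$reconstructed)) " (frame-corrected)" else ""))
  cat("  Cys per domain:",
      paste(sprintf("%s=%d", names(x$cys_positions),
                    lengths(x$cys_positions)), collapse = ", "), "\n")
  invisible(x)
}

#' Per-domain cysteine census
#'
#' Counts cysteine residues in each domain and flags any cysteine
#' "near the C-terminus of the repetitive domain" -- quantified as the
#' final `repeat_terminal_window` residues (default 60) of that domain,
#' a placement diagnostic of typical y-type subunits.
#'
#' @param annotation a `subunit_annotation`.
#' @param translation the residue string the annotation refers to.
#' @param config a [hmwgs_config()].
#' @return `list(counts = named integer, total =, repeat_terminal_cys =)`.
#' @export
cysteine_census <- function(annotation, translation,
                            config = hmwgs_config()) {
  if (nchar(translation) != annotation$total_len) {
    stop("translation length (", nchar(translation),
         ") does not match annotation total_len (",
         annotation$total_len, ")")
  }
  b <- annotation$boundaries
  chars <- strsplit(translation, "")[[1]]
  counts <- vapply(rownames(b), function(d) {
    sum(chars[(b[d, 1] + 1L):b[d, 2]] == "C")
  }, integer(1))
  window <- min(config$repeat_terminal_window,
                b["repetitive", 2] - b["repetitive", 1])
  tail_range <- (b["repetitive", 2] - window + 1L):b["repetitive", 2]
  list(counts = counts, total = sum(counts),
       repeat_terminal_cys = any(chars[tail_range] == "C"))
}
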