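#' Pipeline configuration
#'
#' Collects every tunable numeric used by the annotation, comparison and
#' phylogeny stages. Defaults are the values used throughout the package
#' documentation; any subset can be overridden.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @details
#' Nucleotide alignment scoring (global, affine gaps): `nt_match` (+2),
#' `nt_mismatch` (-1), `gap_opening` (6) and `gap_extension` (0.5), both
#' penalties given as positive numbers. The gap costs are deliberately
#' stiff relative to the mismatch cost so that a whole motif-block indel
#' (18-63 nt) stays in a single gap run instead of fragmenting.
#'
#' `aa_match`/`aa_mismatch` score the protein-level alignments used for
#' anchor location and repetitive-domain comparison.
#'
#' `divergence_floor` is the minimum fraction of identical residue columns
#' (gap columns excluded) below which pairwise comparison refuses to
#' interpret the alignment ("sequences too divergent").
#'
#' `repeat_terminal_window` (60 residues) quantifies "near the C-terminus
#' of the repetitive domain" for the cysteine placement diagnostic.
#'
#' `motif_other_penalty` is the per-residue cost of leaving a residue
#' outside any motif class during decomposition; `motif_tri_bias` is a
#' small surcharge on standalone GQQ tiles so that hexa/nona tilings are
#' preferred when the total edit distance ties.
#'
#' `slice_first_motifs` (3) and `slice_last_motifs` (6) are the number of
#' repetitive-domain segments included in the N-side and C-side phylogeny
#' regions.
#'
#' `signal_min_identity` and `cterm_min_identity` are the minimal
#' fractional identities an anchor template alignment must reach before a
#' domain boundary is accepted.
#'
#' `msa_gap_open` and `msa_gap_ext` are the affine gap costs of the
#' progressive profile aligner, in column-score units.
#'
#' @return A named list of class `hmwgs_config`.
#' @examples
#' cfg <- hmwgs_config(gap_opening = 8)
#' cfg$gap_opening
#' @export
hmwgs_config <- function(...) {
  cfg <- list(
    nt_match = 2,
    nt_mismatch = -1,
    gap_opening = 6,
    gap_extension = 0.5,
    aa_match = 2,
    aa_mismatch = -1,
    divergence_floor = 0.75,
    repeat_terminal_window = 60,
    motif_other_penalty = 1,
    motif_tri_bias = 0.25,
    slice_first_motifs = 3,
    slice_last_motifs = 6,
    signal_min_identity = 0.6,
    cterm_min_identity = 0.5,
    msa_gap_open = 4,
    msa_gap_ext = 1,
    log_level = "warn"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown configuration option(s): ", paste(bad, collapse = ", "))
    }
    cfg <- modifyList(cfg, dots)
  }
  structure(cfg, class = c("hmwgs_config", "list"))
}

log_levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)

hmwgs_log <- function(level, ..., config = NULL) {
  threshold <- if (is.null(config)) "warn" else config$log_level
  if (log_levels[[level]] >= log_levels[[threshold]]) {
    message(sprintf("[%s] %s", toupper(level), paste0(...)))
  }
  invisible(NULL)
}
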