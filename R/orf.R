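# Open-reading-frame analysis: translation, premature-stop detection,
# tandem terminal stop accounting and frameshift localization.

STOP_CODONS <- c("TAA", "TAG", "TGA")

codons_of <- function(sequence, from = 1L) {
  n <- nchar(sequence)
  n_codons <- (n - from + 1L) %/% 3L
  if (n_codons <= 0L) return(character(0))
  starts <- from + 3L * (seq_len(n_codons) - 1L)
  substring(sequence, starts, starts + 2L)
}

#' Translate a DNA string with the standard genetic code
#'
#' Stop codons translate to `"*"`; codons containing non-ACGT characters
#' translate to `"X"`. Trailing bases that do not fill a codon are
#' ignored.
#'
#' @param sequence DNA string.
#' @return Amino-acid string.
#' @export
translate_dna <- function(sequence) {
  cods <- codons_of(toupper(sequence))
  if (!length(cods)) return("")
  aa <- Biostrings::GENETIC_CODE[cods]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Locate and characterize the open reading frame
#'
#' The ORF is anchored at the first ATG and scanned codon-wise with the
#' standard genetic code. Terminal "tandem stop codons" -- the maximal run
#' of consecutive stop codons in the frame anchored at the 3' end of the
#' sequence -- are counted separately from premature in-frame stops, so
#' that a gene with a downstream frameshift still has its terminal stops
#' recognized. Translation stops at the first in-frame stop codon.
#'
#' A record is intact when it has no premature stop and its length from
#' the ATG is a codon multiple; intact records satisfy
#' `length_nt == 3 * (nchar(translation) + tandem_stop_count)`.
#'
#' @param gene a `gene_record`.
#' @return An object of class `orf_record` with fields `gene_id`,
#'   `orf_start`/`orf_end` (0-based half-open nt), `length_nt`
#'   (including the tandem stop codons), `translation`,
#'   `premature_stops` (1-based codon ordinals), `tandem_stop_count`,
#'   `terminated` and `is_intact`.
#' @examples
#' find_orf(gene_record("toy", "ATGAAATAGTGA"))
#' @export
find_orf <- function(gene) {
  stopifnot(inherits(gene, "gene_record"))
  s <- gene$sequence
  if (nchar(s) < 6L) stop("record '", gene$id, "': sequence shorter than 6 nt")
  atg <- regexpr("ATG", s, fixed = TRUE)
  if (atg < 0L) stop("record '", gene$id, "': no ORF (no ATG found)")
  orf_start <- as.integer(atg) - 1L           # 0-based
  orf_end <- nchar(s)                         # 0-based half-open
  length_nt <- orf_end - orf_start

  # terminal tandem stops, frame anchored at the 3' terminus
  tandem <- 0L
  pos <- nchar(s) - 2L
  while (pos >= orf_start + 1L &&
         substr(s, pos, pos + 2L) %in% STOP_CODONS) {
    tandem <- tandem + 1L
    pos <- pos - 3L
  }
  terminal_run_start0 <- nchar(s) - 3L * tandem  # 0-based start of the run

  # codon-wise scan from the ATG
  cods <- codons_of(s, from = orf_start + 1L)
  stop_idx <- which(cods %in% STOP_CODONS)
  # a stop codon is premature when it ends before the terminal run begins
  stop_end0 <- orf_start + 3L * stop_idx
  premature <- stop_idx[stop_end0 <= terminal_run_start0]

  first_stop <- if (length(stop_idx)) stop_idx[1] else length(cods) + 1L
  aa <- Biostrings::GENETIC_CODE[cods[seq_len(first_stop - 1L)]]
  aa[is.na(aa)] <- "X"
  translation <- paste(aa, collapse = "")

  terminated <- tandem > 0L || length(stop_idx) > 0L
  if (!terminated) {
    hmwgs_log("warn", "record '", gene$id,
              "': no stop codon in frame (non-terminated ORF)")
  }
  is_intact <- length(premature) == 0L && length_nt %% 3L == 0L
  structure(
    list(gene_id = gene$id, orf_start = orf_start, orf_end = orf_end,
         length_nt = length_nt, translation = translation,
         premature_stops = as.integer(premature),
         tandem_stop_count = tandem, terminated = terminated,
         is_intact = is_intact),
    class = "orf_record"
  )
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("<orf_record> %s: %d nt, %d aa, %d tandem stop(s)%s\n",
              x$gene_id, x$length_nt, nchar(x$translation),
              x$tandem_stop_count,
              if (x$is_intact) ", intact" else
                sprintf(", NOT intact (%d premature stop(s))",
                        length(x$premature_stops))))
  invisible(x)
}

#' Detect single-base-deletion frameshifts against an intact reference
#'
#' The query is globally aligned to the reference at the nucleotide level
#' (affine gap penalties, gap runs normalized to their leftmost
#' score-equivalent placement). Every single-nucleotide gap in the query
#' row whose downstream net frame offset is non-zero -- i.e. the deletion
#' is not compensated within the alignment, so the downstream in-frame
#' translation diverges -- is reported as a frameshift event. The event
#' coordinate is the 1-based query position of the base immediately
#' following the deletion; in homopolymer runs this is the leftmost
#' equivalent placement.
#'
#' @param query a `gene_record`.
#' @param reference a `gene_record` with an intact ORF.
#' @param config a [hmwgs_config()].
#' @return A list of `frameshift_event` objects (possibly empty), each
#'   with fields `query_id`, `reference_id`, `position` and `context`
#'   (the +/- 10 nt window around the position).
#' @export
detect_frameshift <- function(query, reference, config = hmwgs_config()) {
  stopifnot(inherits(query, "gene_record"), inherits(reference, "gene_record"))
  ref_orf <- find_orf(reference)
  if (!ref_orf$is_intact) {
    stop("reference '", reference$id, "' does not have an intact ORF")
  }
  aln <- align_nt_pair(query$sequence, reference$sequence, config)
  q <- aln$a_chars
  r <- aln$b_chars
  n_col <- length(q)
  q_gap <- q == "-"
  r_gap <- r == "-"
  # net frame offset (query minus reference) after each column
  offset <- cumsum(as.integer(r_gap) - as.integer(q_gap)) %% 3L

  runs <- rle(q_gap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  events <- list()
  q_pos_before <- cumsum(!q_gap)   # query coordinate as of each column
  for (k in which(runs$values & runs$lengths == 1L)) {
    col <- starts[k]
    # offset downstream of this gap: non-zero until compensated elsewhere;
    # require it to persist (>= 30 columns or to the end of the alignment)
    down <- offset[col:min(n_col, col + 29L)]
    if (all(down != 0L)) {
      pos <- q_pos_before[col] + 1L    # base following the deletion
      if (pos > nchar(query$sequence)) next
      ctx_from <- max(1L, pos - 10L)
      ctx_to <- min(nchar(query$sequence), pos + 10L)
      events[[length(events) + 1L]] <- structure(
        list(query_id = query$id, reference_id = reference$id,
             position = pos,
             context = substr(query$sequence, ctx_from, ctx_to)),
        class = "frameshift_event"
      )
    }
  }
  events
}

#' @export
print.frameshift_event <- function(x, ...) {
  cat(sprintf("<frameshift_event> %s vs %s: 1-nt deletion before position %d (%s)\n",
              x$query_id, x$reference_id, x$position, x$context))
  invisible(x)
}

#' Reconstruct the conceptual reading frame of a frameshifted gene
#'
#' Reinserts one `N` at each detected single-base deletion so that the
#' downstream frame matches the intact reference; the codon spanning the
#' insertion translates to `X`. Used to compute the conceptual
#' translation on which pseudogene domain sizes are reported.
#'
#' @param gene a `gene_record`.
#' @param events list of `frameshift_event`s from [detect_frameshift()].
#' @return A `gene_record` with the corrected sequence (ambiguity
#'   allowed) and id suffixed `"|frame-corrected"` kept in `source`.
#' @export
reconstruct_frame <- function(gene, events) {
  s <- gene$sequence
  positions <- sort(vapply(events, `[[`, numeric(1), "position"))
  for (i in seq_along(positions)) {
    p <- positions[i] + (i - 1L)    # earlier insertions shift coordinates
    s <- paste0(substr(s, 1L, p - 1L), "N", substr(s, p, nchar(s)))
  }
  gene_record(gene$id, s, source = paste0(gene$source, "|frame-corrected"),
              description = gene$description, allow_ambiguity = TRUE)
}
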