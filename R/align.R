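# Pairwise global alignment helpers. Alignment itself is delegated to
# Biostrings (Needleman-Wunsch with affine gaps); this file fixes the
# scoring conventions and normalizes gap placement so that downstream
# coordinates are deterministic.
#
# Biostrings gap convention: a run of L gap positions costs
# gapOpening + L * gapExtension (both supplied as positive penalties).

sub_matrix_for <- function(a, b, match, mismatch) {
  chars <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  m <- matrix(mismatch, length(chars), length(chars),
              dimnames = list(chars, chars))
  diag(m) <- match
  m
}

# Leftmost-normalize gap runs in `x` against partner row `y`:
# a run may shift one column left whenever the partner base entering the
# run equals the partner base leaving it, which preserves every column
# score. Repeated to a fixed point so runs can merge.
shift_gaps_left <- function(x, y) {
  repeat {
    changed <- FALSE
    runs <- rle(x == "-")
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      i <- starts[k]; j <- ends[k]
      while (i > 1L && x[i - 1L] != "-" && y[i - 1L] == y[j]) {
        x[j] <- x[i - 1L]
        x[i - 1L] <- "-"
        i <- i - 1L; j <- j - 1L
        changed <- TRUE
      }
    }
    if (!changed) return(x)
  }
}

align_pair <- function(a, b, match, mismatch, gap_opening, gap_extension) {
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = sub_matrix_for(a, b, match, mismatch),
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  a_chars <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b_chars <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  a_chars <- shift_gaps_left(a_chars, b_chars)
  b_chars <- shift_gaps_left(b_chars, a_chars)
  both <- a_chars != "-" & b_chars != "-"
  identity <- if (any(both)) mean(a_chars[both] == b_chars[both]) else 0
  list(a_chars = a_chars, b_chars = b_chars,
       score = Biostrings::score(pa), identity = identity)
}

align_nt_pair <- function(a, b, config = hmwgs_config()) {
  align_pair(a, b, config$nt_match, config$nt_mismatch,
             config$gap_opening, config$gap_extension)
}

align_aa_pair <- function(a, b, config = hmwgs_config()) {
  align_pair(a, b, config$aa_match, config$aa_mismatch,
             config$gap_opening, config$gap_extension)
}

# gap runs of `x_chars` described on the coordinates of the partner
# sequence (the one that has the extra bases); returns a data.frame of
# 1-based inclusive intervals
gap_runs <- function(x_chars, partner_chars) {
  runs <- rle(x_chars == "-")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  partner_pos <- cumsum(partner_chars != "-")
  data.frame(
    col_start = starts[keep],
    col_end = ends[keep],
    length_nt = runs$lengths[keep],
    start = partner_pos[starts[keep]],
    end = partner_pos[ends[keep]],
    sequence = vapply(keep, function(k) {
      paste(partner_chars[starts[k]:ends[k]], collapse = "")
    }, character(1))
  )
}
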