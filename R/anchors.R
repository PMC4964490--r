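# Family-specific anchor templates used for domain segmentation and
# type diagnostics. Shipped as an editable FASTA file so that users
# working on other Triticeae lineages can swap their own consensus in.

#' Load an anchor template set
#'
#' Anchors are the conserved peptides that delimit the four HMW-GS
#' domains: the two signal-peptide variants (21 aa canonical, 18 aa for
#' the hexapeptide-deleted lineage), the two N-terminal consensus
#' templates (105/102 aa, each recording the alignment position of the
#' "extra glutamine" diagnostic via an `extra_q=` tag in the FASTA
#' header), and the 42-aa C-terminal consensus containing the
#' x-type-associated undecapeptide LAAQLPAMCRL. The templates bundled
#' with the package are synthetic consensus sequences that honour the
#' documented anchor features of the family; they are not any one
#' gene's residues.
#'
#' @param path FASTA file of templates; defaults to the bundled set.
#' @return An object of class `anchor_set`.
#' @export
load_anchors <- function(path = system.file("extdata", "anchor_templates.fa",
                                            package = "hmwgs")) {
  set <- Biostrings::readBStringSet(path)
  full <- names(set)
  ids <- sub("\\s.*$", "", full)
  seqs <- setNames(as.character(set), ids)
  need <- c("signal_long21", "signal_short18", "n_terminal_105",
            "n_terminal_102", "c_terminal_42")
  missing <- setdiff(need, ids)
  if (length(missing)) {
    stop("anchor file '", path, "' lacks template(s): ",
         paste(missing, collapse = ", "))
  }
  extra_q <- function(id) {
    hdr <- full[match(id, ids)]
    m <- regmatches(hdr, regexpr("extra_q=[0-9]+", hdr))
    if (!length(m)) return(NA_integer_)
    as.integer(sub("extra_q=", "", m))
  }
  structure(
    list(
      signal = list(long21 = seqs[["signal_long21"]],
                    short18 = seqs[["signal_short18"]]),
      n_terminal = list(
        aa105 = list(sequence = seqs[["n_terminal_105"]],
                     extra_q = extra_q("n_terminal_105")),
        aa102 = list(sequence = seqs[["n_terminal_102"]],
                     extra_q = extra_q("n_terminal_102"))
      ),
      c_terminal = seqs[["c_terminal_42"]],
      terminal_hexapeptide = "SSQ[PT]VQ",
      undecapeptide = "LAAQLPAMCRL",
      path = path
    ),
    class = "anchor_set"
  )
}

anchor_cache <- new.env(parent = emptyenv())

#' Default anchor set
#'
#' Cached copy of the bundled anchor templates (see [load_anchors()]).
#' @return An `anchor_set`.
#' @export
default_anchors <- function() {
  if (is.null(anchor_cache$default)) {
    anchor_cache$default <- load_anchors()
  }
  anchor_cache$default
}

#' @export
print.anchor_set <- function(x, ...) {
  cat("<anchor_set>\n")
  cat("  signal peptides:", nchar(x$signal$long21), "/",
      nchar(x$signal$short18), "aa\n")
  cat("  N-terminal templates:", nchar(x$n_terminal$aa105$sequence), "/",
      nchar(x$n_terminal$aa102$sequence), "aa\n")
  cat("  C-terminal template:", nchar(x$c_terminal), "aa\n")
  invisible(x)
}
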