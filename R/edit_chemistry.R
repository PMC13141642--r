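## Editor chemistries and window-edit enumeration.
##
## CBE deaminates C->T and ABE A->G, always on the guide strand; the genomic
## plus-strand record for a minus-strand guide is the complementary change
## (CBE: G->A, ABE: T->C).  Edits are enumerated at every target base inside
## the editing window (default protospacer positions 4-8); positions outside
## the window can optionally be emitted flagged `out_of_window`.

#' Base-editor definition
#'
#' @param label `"CBE"` (C->T on the guide strand) or `"ABE"` (A->G).
#' @return A list with `label`, `ref` and `alt` guide-strand bases, class
#'   `editor`.
#' @export
editor <- function(label = c("CBE", "ABE")) {
  label <- match.arg(label)
  structure(list(label = label,
                 ref = if (label == "CBE") "C" else "A",
                 alt = if (label == "CBE") "T" else "G"),
            class = "editor")
}

DEFAULT_WINDOW <- c(4L, 8L)

check_window <- function(window) {
  window <- as.integer(window)
  if (length(window) != 2L || window[1L] < 1L || window[2L] > PROTO_LEN ||
      window[1L] > window[2L]) {
    stop("editing window must be [lo, hi] within protospacer positions 1-20")
  }
  window
}

#' Enumerate editor-induced edits for a set of guides
#'
#' One edit per target base (C for CBE, A for ABE) at protospacer positions
#' inside `window`.  With `extended = TRUE`, target bases outside the window
#' are also emitted, flagged `out_of_window`.
#'
#' @param guides A `guide_set` from [find_guides()] (or one row of it).
#' @param editor An [editor()].
#' @param window Editing window `c(lo, hi)`, 1-based protospacer positions.
#' @param extended Also emit out-of-window target positions, flagged.
#' @return A data frame (class `edit_set`) with columns `guide_id`, `chrom`,
#'   `strand`, `pos` (protospacer position), `guide_ref`, `guide_alt`,
#'   `gcoord` (0-based plus-strand), `plus_ref`, `plus_alt`, `editor`,
#'   `out_of_window`.
#' @export
enumerate_edits <- function(guides, editor, window = DEFAULT_WINDOW,
                            extended = FALSE) {
  window <- check_window(window)
  positions <- if (extended) seq_len(PROTO_LEN) else window[1L]:window[2L]
  n <- nrow(guides)
  rows <- vector("list", length(positions))
  for (j in seq_along(positions)) {
    p <- positions[j]
    hit <- substr(guides$protospacer, p, p) == editor$ref
    if (!any(hit)) next
    g <- guides[hit, , drop = FALSE]
    minus <- g$strand == "-"
    gcoord <- ifelse(minus, g$end - p, g$start + (p - 1L))
    rows[[j]] <- data.frame(
      guide_id = g$guide_id, chrom = g$chrom, strand = g$strand,
      pos = p, guide_ref = editor$ref, guide_alt = editor$alt,
      gcoord = as.integer(gcoord),
      plus_ref = ifelse(minus, comp_base(editor$ref), editor$ref),
      plus_alt = ifelse(minus, comp_base(editor$alt), editor$alt),
      editor = editor$label,
      out_of_window = p < window[1L] | p > window[2L],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  e <- if (length(rows)) do.call(rbind, rows) else data.frame(
    guide_id = character(0), chrom = character(0), strand = character(0),
    pos = integer(0), guide_ref = character(0), guide_alt = character(0),
    gcoord = integer(0), plus_ref = character(0), plus_alt = character(0),
    editor = character(0), out_of_window = logical(0),
    stringsAsFactors = FALSE)
  e <- e[order(e$chrom, e$gcoord, e$strand, e$guide_id), , drop = FALSE]
  rownames(e) <- NULL
  structure(e, class = c("edit_set", "data.frame"),
            window = window, editor = editor$label)
}

#' Enumerate window edits for a single guide
#'
#' Convenience single-guide form of [enumerate_edits()].
#'
#' @inheritParams enumerate_edits
#' @param guide One row of a `guide_set`.
#' @return An `edit_set` data frame.
#' @export
enumerate_window_edits <- function(guide, editor, window = DEFAULT_WINDOW,
                                   extended = FALSE) {
  enumerate_edits(guide, editor, window = window, extended = extended)
}

#' Single-codon stop-gain routes of an editor
#'
#' The codon conversions a single in-window base edit can achieve that turn
#' a sense codon into a stop.  For CBE these are the five classical routes
#' (CAA->TAA, CAG->TAG, CGA->TGA by direct C->T; TGG->TAG and TGG->TGA by
#' G->A through an opposite-strand guide).  ABE admits none: no single A->G
#' or T->C change converts a sense codon to a stop.
#'
#' @param editor An [editor()].
#' @return A data frame with columns `ref_codon`, `codon_pos`, `sense_ref`,
#'   `sense_alt`, `alt_codon` (empty for ABE).
#' @export
stop_gain_routes <- function(editor) {
  if (editor$label == "CBE") {
    data.frame(
      ref_codon = c("CAA", "CAG", "CGA", "TGG", "TGG"),
      codon_pos = c(1L, 1L, 1L, 2L, 3L),
      sense_ref = c("C", "C", "C", "G", "G"),
      sense_alt = c("T", "T", "T", "A", "A"),
      alt_codon = c("TAA", "TAG", "TGA", "TAG", "TGA"),
      stringsAsFactors = FALSE)
  } else {
    data.frame(ref_codon = character(0), codon_pos = integer(0),
               sense_ref = character(0), sense_alt = character(0),
               alt_codon = character(0), stringsAsFactors = FALSE)
  }
}

#' Apply a single base edit to a genome
#'
#' Substitutes one base; the plus-strand reference base must match the
#' genome at the edit coordinate, otherwise a hard error is raised (this
#' guards against coordinate-mapping bugs).
#'
#' @param sequences A [genome_sequences] object.
#' @param edit One row of an `edit_set` (needs `chrom`, `gcoord`, `plus_ref`,
#'   `plus_alt`).
#' @return The modified [genome_sequences].
#' @export
apply_edit <- function(sequences, edit) {
  s <- sequences[[edit$chrom]]
  at <- edit$gcoord + 1L
  have <- substr(s, at, at)
  if (have != edit$plus_ref) {
    stop(sprintf("reference mismatch at %s:%d (genome %s, edit expects %s)",
                 edit$chrom, edit$gcoord, have, edit$plus_ref))
  }
  substr(s, at, at) <- edit$plus_alt
  sequences[[edit$chrom]] <- s
  sequences
}

#' Write an edit set as VCF
#'
#' Minimal VCF 4.2: 1-based positions, plus-strand REF/ALT, INFO fields
#' `GUIDE` (guide id), `PPOS` (protospacer position), `EDITOR`, `WINDOW`
#' (`in`/`out`).
#'
#' @param edits An `edit_set`.
#' @param sequences The [genome_sequences] scanned (for contig headers).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edits_vcf <- function(edits, sequences, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=bescan",
           sprintf("##contig=<ID=%s,length=%d>", names(sequences),
                   nchar(sequences)),
           '##INFO=<ID=GUIDE,Number=1,Type=String,Description="Guide id">',
           '##INFO=<ID=PPOS,Number=1,Type=Integer,Description="Protospacer position">',
           '##INFO=<ID=EDITOR,Number=1,Type=String,Description="Base editor">',
           '##INFO=<ID=WINDOW,Number=1,Type=String,Description="in/out of editing window">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tGUIDE=%s;PPOS=%d;EDITOR=%s;WINDOW=%s",
                  edits$chrom, edits$gcoord + 1L, edits$plus_ref,
                  edits$plus_alt, edits$guide_id, edits$pos, edits$editor,
                  ifelse(edits$out_of_window, "out", "in"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
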