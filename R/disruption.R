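## Classification of window edits into the three gene-disruption strategies
## (premature stop, start-codon loss, splice-signal disruption) and
## prediction of the transcript consequence of each candidate.

candidate_columns <- function() {
  data.frame(
    gene_id = character(0), guide_id = character(0), editor = character(0),
    strategy = character(0), subsite = character(0),
    codon_index = integer(0), ref_codon = character(0), alt_codon = character(0),
    within_quarter = logical(0), tier = integer(0), intron_index = integer(0),
    chrom = character(0), gcoord = integer(0),
    plus_ref = character(0), plus_alt = character(0), pos = integer(0),
    stringsAsFactors = FALSE)
}

## assemble classifier output (a list of per-candidate lists) into the
## canonical candidate data frame
bind_candidates <- function(gene, rows) {
  if (length(rows) == 0L) return(candidate_columns())
  pull <- function(field) {
    v <- lapply(rows, `[[`, field)
    unlist(v, use.names = FALSE)
  }
  data.frame(
    gene_id = gene$gene_id, guide_id = pull("guide_id"),
    editor = pull("editor"), strategy = pull("strategy"),
    subsite = pull("subsite"), codon_index = pull("codon_index"),
    ref_codon = pull("ref_codon"), alt_codon = pull("alt_codon"),
    within_quarter = pull("within_quarter"), tier = pull("tier"),
    intron_index = pull("intron_index"), chrom = pull("chrom"),
    gcoord = pull("gcoord"), plus_ref = pull("plus_ref"),
    plus_alt = pull("plus_alt"), pos = pull("pos"),
    stringsAsFactors = FALSE)
}

## coding-strand ref/alt of an edit relative to a gene
coding_change <- function(gene, edit) {
  if (gene$strand == "+") c(edit$plus_ref, edit$plus_alt)
  else c(comp_base(edit$plus_ref), comp_base(edit$plus_alt))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Premature stop-codon candidates for one gene
#'
#' For every in-window edit falling inside the spliced CDS, the affected
#' codon is recomputed on the coding strand; a candidate is emitted iff the
#' single edit converts a non-stop codon into `TAA`/`TAG`/`TGA`.  Edits at
#' the final (terminator) codon are excluded.  `within_quarter` is `TRUE`
#' when the codon index is at most `ceiling(quarter * total codons)`.
#'
#' @param gene A complete gene model.
#' @param edits An `edit_set` (out-of-window edits are ignored).
#' @param sequences The [genome_sequences].
#' @param quarter 5'-fraction of the CDS in which a premature stop is
#'   counted as reliably inactivating (default 0.25).
#' @return A candidate data frame (see [design_candidates()]).
#' @export
stop_candidates <- function(gene, edits, sequences, quarter = 0.25) {
  out <- list()
  if (!gene$complete) return(candidate_columns())
  cds_seq <- spliced_cds(gene, sequences)
  n_codons <- gene$n_codons
  q_limit <- ceiling(quarter * n_codons)
  e <- as.list(edits[!edits$out_of_window & edits$chrom == gene$chrom, ,
                     drop = FALSE])
  minus <- gene$strand == "-"
  for (i in seq_along(e$gcoord)) {
    cpos <- cds_position(gene, e$gcoord[i])
    if (is.na(cpos)) next
    ci <- (cpos - 1L) %/% 3L + 1L
    if (ci >= n_codons) next               # terminator codon
    within <- (cpos - 1L) %% 3L + 1L
    ref_codon <- substr(cds_seq, 3L * ci - 2L, 3L * ci)
    ref <- if (minus) comp_base(e$plus_ref[i]) else e$plus_ref[i]
    alt <- if (minus) comp_base(e$plus_alt[i]) else e$plus_alt[i]
    if (substr(ref_codon, within, within) != ref) {
      stop("internal error: CDS base does not match edit reference")
    }
    alt_codon <- ref_codon
    substr(alt_codon, within, within) <- alt
    if (ref_codon %in% STOP_CODONS || !(alt_codon %in% STOP_CODONS)) next
    out[[length(out) + 1L]] <- list(
      guide_id = e$guide_id[i], editor = e$editor[i], gcoord = e$gcoord[i],
      plus_ref = e$plus_ref[i], plus_alt = e$plus_alt[i], pos = e$pos[i],
      chrom = e$chrom[i],
      strategy = "premature_stop", subsite = NA_character_,
      codon_index = ci, ref_codon = ref_codon, alt_codon = alt_codon,
      within_quarter = ci <= q_limit, tier = 1L, intron_index = NA_integer_)
  }
  bind_candidates(gene, out)
}

#' Start-codon loss candidates for one gene
#'
#' Candidates are in-window edits hitting the first CDS codon that change
#' `ATG` into anything else.  The chemistry permits ABE `ATG->GTG` (position
#' 1) and `ATG->ACG` (position 2, via an opposite-strand guide), and CBE
#' `ATG->ATA` (position 3, via an opposite-strand guide).
#'
#' @inheritParams stop_candidates
#' @return A candidate data frame.
#' @export
start_candidates <- function(gene, edits, sequences) {
  out <- list()
  if (!gene$complete) return(candidate_columns())
  cds_seq <- spliced_cds(gene, sequences)
  if (substr(cds_seq, 1L, 3L) != "ATG") return(candidate_columns())
  e <- as.list(edits[!edits$out_of_window & edits$chrom == gene$chrom, ,
                     drop = FALSE])
  minus <- gene$strand == "-"
  for (i in seq_along(e$gcoord)) {
    cpos <- cds_position(gene, e$gcoord[i])
    if (is.na(cpos) || cpos > 3L) next
    alt <- if (minus) comp_base(e$plus_alt[i]) else e$plus_alt[i]
    alt_codon <- "ATG"
    substr(alt_codon, cpos, cpos) <- alt
    if (alt_codon == "ATG") next
    out[[length(out) + 1L]] <- list(
      guide_id = e$guide_id[i], editor = e$editor[i], gcoord = e$gcoord[i],
      plus_ref = e$plus_ref[i], plus_alt = e$plus_alt[i], pos = e$pos[i],
      chrom = e$chrom[i],
      strategy = "start_loss", subsite = NA_character_,
      codon_index = 1L, ref_codon = "ATG", alt_codon = alt_codon,
      within_quarter = NA, tier = 1L, intron_index = NA_integer_)
  }
  bind_candidates(gene, out)
}

#' Splice-signal disruption candidates for one gene
#'
#' Every in-window edit inside an intron becomes a candidate.  The subsite
#' is `donor` for intron positions 1-2 (the GT), `acceptor` for the final
#' two positions (the AG), `branch_region` for coding-strand adenines within
#' the 3'-terminal `branch_window` nucleotides, else `other_intronic`.
#' Donor/acceptor candidates are tier 1; the rest tier 2, reflecting that
#' edits away from the terminal dinucleotides disrupt splicing much less
#' reliably.
#'
#' @inheritParams stop_candidates
#' @param branch_window Width (nt) of the 3'-terminal intron region searched
#'   for branch-point adenines (default 50).
#' @return A candidate data frame.
#' @export
splice_candidates <- function(gene, edits, sequences, branch_window = 50L) {
  out <- list()
  if (nrow(gene$introns) == 0L) return(candidate_columns())
  e <- as.list(edits[!edits$out_of_window & edits$chrom == gene$chrom, ,
                     drop = FALSE])
  minus <- gene$strand == "-"
  for (i in seq_along(e$gcoord)) {
    ip <- intron_position(gene, e$gcoord[i])
    if (is.na(ip)) next
    off <- attr(ip, "offset")
    row <- if (minus) nrow(gene$introns) - as.integer(ip) + 1L else as.integer(ip)
    ilen <- gene$introns[row, 2L] - gene$introns[row, 1L]
    ref <- if (minus) comp_base(e$plus_ref[i]) else e$plus_ref[i]
    subsite <-
      if (off <= 2L) "donor"
      else if (off >= ilen - 1L) "acceptor"
      else if (off > ilen - branch_window && ref == "A") "branch_region"
      else "other_intronic"
    out[[length(out) + 1L]] <- list(
      guide_id = e$guide_id[i], editor = e$editor[i], gcoord = e$gcoord[i],
      plus_ref = e$plus_ref[i], plus_alt = e$plus_alt[i], pos = e$pos[i],
      chrom = e$chrom[i],
      strategy = "splice_disruption", subsite = subsite,
      codon_index = NA_integer_, ref_codon = NA_character_,
      alt_codon = NA_character_, within_quarter = NA,
      tier = if (subsite %in% c("donor", "acceptor")) 1L else 2L,
      intron_index = as.integer(ip))
  }
  bind_candidates(gene, out)
}

#' Simulate retention of one intron
#'
#' Builds the mutant mature transcript -- the spliced CDS with the intron
#' sequence re-inserted at its position -- translates it from the start
#' codon, and reports the first stop codon, the truncated protein length,
#' and whether the retained intron shifts the reading frame (length not a
#' multiple of three).
#'
#' @param gene A complete gene model.
#' @param intron_index Intron index in transcription order (1-based).
#' @param sequences The [genome_sequences].
#' @return A list of class `consequence`: `kind = "intron_retention"`,
#'   `intron_index`, `intron_length`, `frameshift`, `ptc_codon` (first stop
#'   codon index in the mutant frame, NA if none), `truncated_length` (aa).
#' @export
simulate_intron_retention <- function(gene, intron_index, sequences) {
  if (intron_index < 1L || intron_index > nrow(gene$introns)) {
    stop("intron index out of range for gene ", gene$gene_id)
  }
  cds_seq <- spliced_cds(gene, sequences)
  iseq <- intron_seq(gene, intron_index, sequences)
  offset <- cds_nt_before_intron(gene, intron_index)
  mutant <- paste0(substr(cds_seq, 1L, offset), iseq,
                   substr(cds_seq, offset + 1L, nchar(cds_seq)))
  ## translate from the original start codon
  frame_seq <- if (offset == 0L) substr(mutant, nchar(iseq) + 1L, nchar(mutant))
               else mutant
  aa <- translate_dna(frame_seq)
  first_stop <- regexpr("*", aa, fixed = TRUE)
  ptc <- if (first_stop == -1L) NA_integer_ else as.integer(first_stop)
  structure(list(
    kind = "intron_retention",
    intron_index = as.integer(intron_index),
    intron_length = nchar(iseq),
    frameshift = nchar(iseq) %% 3L != 0L,
    ptc_codon = ptc,
    truncated_length = if (is.na(ptc)) NA_integer_ else ptc - 1L
  ), class = "consequence")
}

## number of coding nucleotides transcribed before intron `index`
cds_nt_before_intron <- function(gene, index) {
  intr <- gene$introns
  row <- if (gene$strand == "+") index else nrow(intr) - index + 1L
  cds <- gene$cds
  if (gene$strand == "+") {
    sum(pmax(0L, pmin(cds[, 2L], intr[row, 1L]) - cds[, 1L]))
  } else {
    sum(pmax(0L, cds[, 2L] - pmax(cds[, 1L], intr[row, 2L])))
  }
}

#' Predict the transcript consequence of a disruption candidate
#'
#' `premature_stop` yields a nonsense consequence truncating the protein at
#' the candidate codon; `start_loss` reports loss of the initiator together
#' with the next in-frame ATG (informational); `splice_disruption` delegates
#' to [simulate_intron_retention()] for the candidate's intron.
#'
#' @param gene A complete gene model.
#' @param candidate One row of a candidate data frame.
#' @param sequences The [genome_sequences].
#' @return A list of class `consequence`.
#' @export
predict_consequence <- function(gene, candidate, sequences) {
  switch(candidate$strategy,
    premature_stop = structure(list(
      kind = "nonsense",
      ptc_codon = candidate$codon_index,
      truncated_length = candidate$codon_index - 1L,
      frameshift = FALSE
    ), class = "consequence"),
    start_loss = {
      cds_seq <- spliced_cds(gene, sequences)
      n <- gene$n_codons
      codons <- substring(cds_seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
      nxt <- which(codons[-1L] == "ATG")
      structure(list(
        kind = "start_loss",
        next_inframe_atg = if (length(nxt)) nxt[1L] + 1L else NA_integer_,
        frameshift = FALSE
      ), class = "consequence")
    },
    splice_disruption = simulate_intron_retention(gene, candidate$intron_index,
                                                  sequences),
    stop("unknown strategy: ", candidate$strategy)
  )
}

#' @export
print.consequence <- function(x, ...) {
  cat("consequence:", x$kind)
  if (!is.null(x$ptc_codon)) cat(", first stop at codon", x$ptc_codon)
  if (!is.null(x$truncated_length) && !is.na(x$truncated_length %||% NA)) {
    cat(sprintf(" (%d aa retained)", x$truncated_length))
  }
  if (isTRUE(x$frameshift)) cat(", frameshift")
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Design all disruption candidates for a genome
#'
#' Runs the full scan-and-classify pipeline: guide scanning under the given
#' PAM mode, window-edit enumeration for each requested editor, and
#' candidate classification for each complete gene.
#'
#' @param sequences A [genome_sequences] object.
#' @param models A `gene_model_list` from [read_gff()].
#' @param editors Character vector among `"CBE"`, `"ABE"`.
#' @param pam PAM mode, `"NGG"` or `"NG"`.
#' @param window Editing window (protospacer positions, default `c(4, 8)`).
#' @param quarter 5'-quarter fraction for the premature-stop rule.
#' @param branch_window 3'-intronic branch-region width in nt.
#' @param strategies Subset of
#'   `c("premature_stop", "start_loss", "splice_disruption")`.
#' @return A data frame of candidates (class `candidate_set`) carrying the
#'   run parameters as attribute `params`.
#' @export
design_candidates <- function(sequences, models,
                              editors = c("CBE", "ABE"),
                              pam = c("NGG", "NG"),
                              window = DEFAULT_WINDOW,
                              quarter = 0.25,
                              branch_window = 50L,
                              strategies = c("premature_stop", "start_loss",
                                             "splice_disruption")) {
  pam <- match.arg(pam)
  window <- check_window(window)
  guides <- find_guides(sequences, mode = pam)
  out <- list()
  for (ed_label in editors) {
    ed <- editor(ed_label)
    edits <- enumerate_edits(guides, ed, window = window)
    for (gene in models) {
      span <- range(gene$exons, gene$cds)
      near <- edits[edits$chrom == gene$chrom &
                    edits$gcoord >= span[1L] & edits$gcoord < span[2L], ,
                    drop = FALSE]
      if (nrow(near) == 0L) next
      if ("premature_stop" %in% strategies && gene$complete) {
        out[[length(out) + 1L]] <- stop_candidates(gene, near, sequences,
                                                   quarter = quarter)
      }
      if ("start_loss" %in% strategies && gene$complete) {
        out[[length(out) + 1L]] <- start_candidates(gene, near, sequences)
      }
      if ("splice_disruption" %in% strategies) {
        out[[length(out) + 1L]] <- splice_candidates(gene, near, sequences,
                                                     branch_window = branch_window)
      }
    }
  }
  cand <- if (length(out)) do.call(rbind, out) else candidate_columns()
  cand <- cand[order(cand$gene_id, cand$strategy, cand$gcoord, cand$editor,
                     cand$guide_id), , drop = FALSE]
  rownames(cand) <- NULL
  structure(cand, class = c("candidate_set", "data.frame"),
            params = list(pam = pam, window = window, quarter = quarter,
                          branch_window = branch_window, editors = editors,
                          strategies = strategies))
}

#' @export
print.candidate_set <- function(x, ...) {
  p <- attr(x, "params")
  if (is.null(p)) return(NextMethod())
  cat(sprintf("candidate_set: %d candidate(s) [pam=%s window=%d-%d]\n",
              nrow(x), p$pam, p$window[1], p$window[2]))
  if (nrow(x) && all(c("editor", "strategy") %in% names(x))) {
    print(table(x$editor, x$strategy))
  }
  invisible(x)
}

#' Write a candidate table as TSV
#'
#' Includes a VCF-style 1-based coordinate column alongside the internal
#' 0-based one.
#'
#' @param candidates A `candidate_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  df <- as.data.frame(candidates)
  df$pos_1based <- df$gcoord + 1L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
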