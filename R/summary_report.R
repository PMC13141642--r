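## Genome-wide targetability aggregation: per-gene boolean flags and a
## summary table of gene counts per (editor x strategy x PAM), with union
## ("any disruption") semantics and printed-scale percentages.
##
## Splice-disruption candidates are deliberately excluded from the summary
## counts: "any disruption" is defined as the union of start-codon mutation
## and premature-stop introduction only.  Splice candidates remain available
## in the candidate table and the per-gene flag table as a separate column.

EDITORS <- c("CBE", "ABE")
PAMS <- c("NGG", "NG")

## round half up (R's round() is banker's rounding)
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Per-gene targetability flags
#'
#' Reduces a candidate set to one row per gene with boolean flags per
#' (editor, strategy).  The premature-stop flag requires
#' `within_quarter = TRUE`; splice candidates are reported in their own
#' columns and do not contribute to start/stop flags.
#'
#' @param candidates A `candidate_set` for one PAM mode.
#' @param gene_ids Gene ids to report (typically all complete genes);
#'   genes without candidates get all-FALSE rows.
#' @return A data frame with columns `gene_id`, `<editor>_start`,
#'   `<editor>_stop`, `<editor>_splice` for CBE and ABE.
#' @export
gene_targetability <- function(candidates, gene_ids) {
  out <- data.frame(gene_id = gene_ids, stringsAsFactors = FALSE)
  for (ed in EDITORS) {
    sub <- candidates[candidates$editor == ed, , drop = FALSE]
    stop_ok <- unique(sub$gene_id[sub$strategy == "premature_stop" &
                                  sub$within_quarter %in% TRUE])
    start_ok <- unique(sub$gene_id[sub$strategy == "start_loss"])
    splice_ok <- unique(sub$gene_id[sub$strategy == "splice_disruption"])
    out[[paste0(ed, "_stop")]] <- gene_ids %in% stop_ok
    out[[paste0(ed, "_start")]] <- gene_ids %in% start_ok
    out[[paste0(ed, "_splice")]] <- gene_ids %in% splice_ok
  }
  out
}

#' Genome-wide targetability summary
#'
#' Runs the full pipeline (guide scan, window-edit enumeration, candidate
#' classification, per-gene flags) for both PAM modes and both editors, and
#' counts genes targetable per (editor, strategy, PAM).  Counts are
#' gene-level: a gene counts once however many candidates it has.  The
#' "any" strategy is the per-gene union of start and stop; the "Either"
#' editor row is the per-gene union over editors.
#'
#' @param sequences A [genome_sequences] object.
#' @param models A `gene_model_list`.
#' @param window Editing window (default `c(4, 8)`).
#' @param quarter 5'-quarter fraction (default 0.25).
#' @param branch_window Branch-region width in nt (default 50).
#' @return An object of class `targetability_summary`: list with
#'   `total_genes`, `n_excluded` (incomplete models), `counts` (3-d array
#'   editor x strategy x pam, editors CBE/ABE/Either, strategies
#'   start/stop/any), `percent` (same shape, printed scale, one decimal),
#'   `flags` (per-gene flag table per PAM), `splice_counts`, and `params`.
#' @export
summarize_targetability <- function(sequences, models,
                                    window = DEFAULT_WINDOW,
                                    quarter = 0.25,
                                    branch_window = 50L) {
  complete <- vapply(models, `[[`, logical(1), "complete")
  if (!any(complete)) stop("no complete gene models to summarize")
  genes <- vapply(models[complete], `[[`, character(1), "gene_id")
  total <- length(genes)

  counts <- array(0L,
                  dim = c(3L, 3L, 2L),
                  dimnames = list(editor = c(EDITORS, "Either"),
                                  strategy = c("start", "stop", "any"),
                                  pam = PAMS))
  splice_counts <- array(0L, dim = c(2L, 2L),
                         dimnames = list(editor = EDITORS, pam = PAMS))
  flags <- list()
  for (pam in PAMS) {
    cand <- design_candidates(sequences, models, editors = EDITORS, pam = pam,
                              window = window, quarter = quarter,
                              branch_window = branch_window)
    fl <- gene_targetability(cand, genes)
    flags[[pam]] <- fl
    either_start <- fl$CBE_start | fl$ABE_start
    either_stop <- fl$CBE_stop | fl$ABE_stop
    for (ed in EDITORS) {
      st <- fl[[paste0(ed, "_start")]]
      sp <- fl[[paste0(ed, "_stop")]]
      counts[ed, "start", pam] <- sum(st)
      counts[ed, "stop", pam] <- sum(sp)
      counts[ed, "any", pam] <- sum(st | sp)
      splice_counts[ed, pam] <- sum(fl[[paste0(ed, "_splice")]])
    }
    counts["Either", "start", pam] <- sum(either_start)
    counts["Either", "stop", pam] <- sum(either_stop)
    counts["Either", "any", pam] <- sum(either_start | either_stop)
  }

  res <- structure(list(
    total_genes = total,
    n_excluded = sum(!complete),
    counts = counts,
    percent = round_half_up(100 * counts / total, 1L),
    splice_counts = splice_counts,
    flags = flags,
    params = list(window = window, quarter = quarter,
                  branch_window = branch_window,
                  pam_dialect = "NG = any base then G, 2-nt functional PAM")
  ), class = "targetability_summary")
  validate_summary(res)
  res
}

## structural invariants asserted on every summary
validate_summary <- function(s) {
  co <- s$counts
  stopifnot(
    all(co >= 0L),
    all(co[, , "NG"] >= co[, , "NGG"]),
    all(co["ABE", "stop", ] == 0L),
    all(co["Either", "stop", ] == co["CBE", "stop", ]),
    all(co[, "any", ] >= pmax(co[, "start", ], co[, "stop", ])),
    all(co[, "any", ] <= co[, "start", ] + co[, "stop", ]),
    all(co["Either", , ] >= pmax(co["CBE", , ], co["ABE", , ])),
    all(co["Either", , ] <= co["CBE", , ] + co["ABE", , ])
  )
  invisible(s)
}

#' Percentage of genes targetable, on the printed scale
#'
#' @param count Gene count.
#' @param total Total annotated genes.
#' @return `100 * count / total`, rounded half-up to one decimal.
#' @export
targetable_percent <- function(count, total) {
  round_half_up(100 * count / total, 1L)
}

#' Relative increase from PAM relaxation
#'
#' The percent increase in targetable genes from NGG to NG.
#'
#' @param count_ngg Gene count under NGG.
#' @param count_ng Gene count under NG.
#' @return `100 * (count_ng - count_ngg) / count_ngg`, rounded half-up to
#'   an integer; `NA` when `count_ngg` is zero.
#' @export
relative_increase <- function(count_ngg, count_ng) {
  if (count_ngg == 0) return(NA_real_)
  round_half_up(100 * (count_ng - count_ngg) / count_ngg, 0L)
}

#' @export
print.targetability_summary <- function(x, ...) {
  cat(render_table(x, format = "tsv"))
  invisible(x)
}

#' Render a targetability summary
#'
#' @param summary A `targetability_summary`.
#' @param format `"tsv"` (tab-separated text table with a metadata block) or
#'   `"json"`.
#' @return A single character string.
#' @export
render_table <- function(summary, format = c("tsv", "json")) {
  format <- match.arg(format)
  co <- summary$counts
  pc <- summary$percent
  if (format == "json") {
    obj <- list(
      total_genes = summary$total_genes,
      excluded_incomplete = summary$n_excluded,
      counts = lapply(dimnames(co)$editor, function(ed) {
        l <- list(editor = ed)
        for (st in dimnames(co)$strategy) for (pam in PAMS) {
          key <- paste(st, pam, sep = "_")
          l[[key]] <- if (ed == "ABE" && st == "stop") NA else co[ed, st, pam]
          if (st == "any") l[[paste0(key, "_pct")]] <- pc[ed, st, pam]
        }
        l
      }),
      splice_genes = as.list(as.data.frame(as.table(summary$splice_counts))),
      metadata = summary$params
    )
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                            pretty = TRUE))
  }
  fmt_cell <- function(ed, st, pam) {
    if (ed == "ABE" && st == "stop") return("-")
    if (st == "any") sprintf("%d (%.1f%%)", co[ed, st, pam], pc[ed, st, pam])
    else sprintf("%d", co[ed, st, pam])
  }
  lines <- c(
    paste(c("Editor",
            "start_NGG", "start_NG", "stop_NGG", "stop_NG",
            "any_NGG", "any_NG"), collapse = "\t"))
  for (ed in dimnames(co)$editor) {
    lines <- c(lines, paste(c(ed,
      fmt_cell(ed, "start", "NGG"), fmt_cell(ed, "start", "NG"),
      fmt_cell(ed, "stop", "NGG"), fmt_cell(ed, "stop", "NG"),
      fmt_cell(ed, "any", "NGG"), fmt_cell(ed, "any", "NG")),
      collapse = "\t"))
  }
  meta <- summary$params
  lines <- c(lines, "",
    sprintf("# total_genes=%d excluded_incomplete=%d", summary$total_genes,
            summary$n_excluded),
    sprintf("# window=%d-%d quarter=%g branch_window=%d",
            meta$window[1], meta$window[2], meta$quarter, meta$branch_window),
    sprintf("# pam_dialect=%s", meta$pam_dialect),
    "# any = union(start, stop) per gene; splice disruption reported separately",
    sprintf("# splice-capable genes: CBE NGG=%d NG=%d; ABE NGG=%d NG=%d",
            summary$splice_counts["CBE", "NGG"], summary$splice_counts["CBE", "NG"],
            summary$splice_counts["ABE", "NGG"], summary$splice_counts["ABE", "NG"]))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a JSON summary rendering back into count form
#'
#' Inverse of `render_table(..., format = "json")` for the count fields.
#'
#' @param json JSON string from [render_table()].
#' @return A list with `total_genes` and the counts array.
#' @export
parse_summary_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  co <- array(0L, dim = c(3L, 3L, 2L),
              dimnames = list(editor = c(EDITORS, "Either"),
                              strategy = c("start", "stop", "any"),
                              pam = PAMS))
  for (l in obj$counts) {
    for (st in c("start", "stop", "any")) for (pam in PAMS) {
      v <- l[[paste(st, pam, sep = "_")]]
      co[l$editor, st, pam] <- if (is.null(v)) 0L else as.integer(v)
    }
  }
  list(total_genes = obj$total_genes, counts = co)
}
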