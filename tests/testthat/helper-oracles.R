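# Independent naive oracles used to cross-check the vectorized scanner and
# the candidate classifiers.  Everything here works position by position with
# substr() and an explicit codon table; none of it shares code with the
# package internals it checks.

ORACLE_CODE <- local({
  b <- c("T", "C", "A", "G")
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  codons <- as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
  stats::setNames(aa, codons)
})

oracle_translate <- function(dna) {
  n <- nchar(dna) %/% 3
  paste(ORACLE_CODE[substring(dna, 3 * seq_len(n) - 2, 3 * seq_len(n))],
        collapse = "")
}

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# Position-by-position guide enumeration; returns the same columns as
# find_guides() but derived by brute force.
oracle_find_guides <- function(sequences, mode) {
  pw <- if (mode == "NGG") 3L else 2L
  rows <- list()
  for (chrom in names(sequences)) {
    s <- sequences[[chrom]]
    L <- nchar(s)
    for (a in seq_len(L)) {                       # 1-based protospacer start
      if (a + 19 > L) break
      proto <- substr(s, a, a + 19)
      if (grepl("N", proto, fixed = TRUE)) next
      # forward
      if (a + 19 + pw <= L) {
        pam <- substr(s, a + 20, a + 19 + pw)
        ok <- if (mode == "NGG") {
          substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G"
        } else substr(pam, 2, 2) == "G"
        if (ok && !grepl("N", pam, fixed = TRUE)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, strand = "+", start = a - 1L, end = a + 19L,
            protospacer = proto, pam = pam, stringsAsFactors = FALSE)
        }
      }
      # reverse: guide reads revcomp(proto); its PAM is revcomp of the
      # pw bases immediately 5' of the slice on the plus strand
      if (a - pw >= 1) {
        pam_plus <- substr(s, a - pw, a - 1)
        pam <- oracle_revcomp(pam_plus)
        ok <- if (mode == "NGG") {
          substr(pam, 2, 2) == "G" && substr(pam, 3, 3) == "G"
        } else substr(pam, 2, 2) == "G"
        if (ok && !grepl("N", pam, fixed = TRUE)) {
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = chrom, strand = "-", start = a - 1L, end = a + 19L,
            protospacer = oracle_revcomp(proto), pam = pam,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               protospacer = character(0), pam = character(0))
  out <- out[order(out$chrom, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# Brute-force stop-gain chemistry: every codon x position x single-base
# conversion an editor can make on either strand.
oracle_stop_gain <- function(editor_label) {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  stops <- c("TAA", "TAG", "TGA")
  conv <- if (editor_label == "CBE") {
    list(c("C", "T"), c("G", "A"))   # guide strand C>T; opposite strand -> G>A
  } else {
    list(c("A", "G"), c("T", "C"))
  }
  rows <- list()
  for (cod in setdiff(codons, stops)) {
    for (p in 1:3) {
      for (cv in conv) {
        if (substr(cod, p, p) != cv[1]) next
        alt <- cod
        substr(alt, p, p) <- cv[2]
        if (alt %in% stops) {
          rows[[length(rows) + 1L]] <- data.frame(
            ref_codon = cod, codon_pos = p, alt_codon = alt,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) unique(do.call(rbind, rows)) else
    data.frame(ref_codon = character(0), codon_pos = integer(0),
               alt_codon = character(0))
}

# Verify one reported candidate from first principles (raw sequence +
# annotation intervals only).  Returns TRUE or a string describing the
# failure.
oracle_verify_candidate <- function(cand, sequences, models, pam_mode,
                                    window = c(4, 8)) {
  s <- sequences[[cand$chrom]]
  gene <- Filter(function(m) m$gene_id == cand$gene_id, models)[[1]]
  # guide geometry from the guide id
  gp <- regmatches(cand$guide_id,
                   regexec("^(.+):(\\d+)-(\\d+):([+-])$", cand$guide_id))[[1]]
  gstart <- as.integer(gp[3]); gend <- as.integer(gp[4]); gstrand <- gp[5]
  slice <- substr(s, gstart + 1, gend)
  proto <- if (gstrand == "+") slice else oracle_revcomp(slice)
  pw <- if (pam_mode == "NGG") 3L else 2L
  pam <- if (gstrand == "+") substr(s, gend + 1, gend + pw)
         else oracle_revcomp(substr(s, gstart - pw + 1, gstart))
  if (substr(pam, 2, 2) != "G") return("PAM position 2 not G")
  if (pam_mode == "NGG" && substr(pam, 3, 3) != "G") return("PAM position 3 not G")
  # edited base and window
  p <- if (gstrand == "+") cand$gcoord - gstart + 1L else gend - cand$gcoord
  if (p < window[1] || p > window[2]) return("edit outside window")
  target <- if (cand$editor == "CBE") "C" else "A"
  gbase <- substr(proto, p, p)
  if (gbase != target) return("guide base is not the editor target")
  if (substr(s, cand$gcoord + 1, cand$gcoord + 1) != cand$plus_ref) {
    return("plus_ref mismatch")
  }
  if (cand$strategy == "premature_stop" || cand$strategy == "start_loss") {
    # recompute the codon from the CDS segments
    cds <- gene$cds
    parts <- vapply(seq_len(nrow(cds)),
                    function(i) substr(s, cds[i, 1] + 1, cds[i, 2]),
                    character(1))
    cds_seq <- paste(parts, collapse = "")
    if (gene$strand == "-") cds_seq <- oracle_revcomp(cds_seq)
    # CDS offset of the edited base
    offs <- integer(0)
    for (i in seq_len(nrow(cds))) offs <- c(offs, cds[i, 1]:(cds[i, 2] - 1))
    hit <- match(cand$gcoord, offs)
    if (is.na(hit)) return("edit not in CDS")
    cpos <- if (gene$strand == "+") hit else length(offs) - hit + 1L
    ci <- (cpos - 1) %/% 3 + 1
    if (ci != cand$codon_index &&
        !(cand$strategy == "start_loss" && ci == 1)) return("codon index wrong")
    ref_codon <- substr(cds_seq, 3 * ci - 2, 3 * ci)
    if (cand$strategy == "premature_stop") {
      if (ref_codon != cand$ref_codon) return("ref codon wrong")
      alt <- ref_codon
      k <- (cpos - 1) %% 3 + 1
      base <- if (gene$strand == "+") cand$plus_alt else
        c(A = "T", C = "G", G = "C", T = "A")[[cand$plus_alt]]
      substr(alt, k, k) <- base
      if (!(alt %in% c("TAA", "TAG", "TGA"))) return("alt codon not a stop")
      if (alt != cand$alt_codon) return("alt codon wrong")
    }
  } else if (cand$strategy == "splice_disruption") {
    intr <- gene$introns
    inside <- any(cand$gcoord >= intr[, 1] & cand$gcoord < intr[, 2])
    if (!inside) return("splice edit not in an intron")
  }
  TRUE
}

# Mirror a genome and its gene models through reverse complementation:
# used by the strand-symmetry property tests.
mirror_genome <- function(sim) {
  L <- nchar(sim$sequences[[1]])
  chrom <- names(sim$sequences)
  seqs <- genome_sequences(stats::setNames(revcomp(sim$sequences[[1]]), chrom))
  models <- lapply(sim$models, function(m) {
    mir <- function(iv) {
      out <- cbind(L - iv[, 2], L - iv[, 1])
      out[rev(seq_len(nrow(out))), , drop = FALSE]
    }
    bescan:::build_gene_model(
      gene_id = m$gene_id, mrna_id = m$mrna_id, chrom = chrom,
      strand = if (m$strand == "+") "-" else "+",
      exons = mir(m$exons), cds = mir(m$cds), sequences = seqs)
  })
  class(models) <- "gene_model_list"
  list(sequences = seqs, models = models)
}

# Write a toy gene (single chromosome) as FASTA + GFF3 temp files and load
# them back through the public readers.  `exons` are 0-based half-open
# intervals in chromosome coordinates.
toy_gene_files <- function(chrom_seq, exons, strand = "+", gene_id = "toy",
                           cds = exons, chrom = "chrT") {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(paste0(">", chrom), chrom_seq), fa)
  span <- c(min(exons[, 1], cds[, 1]) + 1, max(exons[, 2], cds[, 2]))
  lines <- c("##gff-version 3",
             sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     chrom, span[1], span[2], strand, gene_id),
             sprintf("%s\ttest\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                     chrom, span[1], span[2], strand, gene_id, gene_id))
  for (i in seq_len(nrow(exons))) {
    lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
                              chrom, exons[i, 1] + 1, exons[i, 2], strand,
                              gene_id, i, gene_id))
  }
  for (i in seq_len(nrow(cds))) {
    lines <- c(lines, sprintf("%s\ttest\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s.t1",
                              chrom, cds[i, 1] + 1, cds[i, 2], strand,
                              gene_id, i, gene_id))
  }
  gff <- tempfile(fileext = ".gff3")
  writeLines(lines, gff)
  list(fa = fa, gff = gff)
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
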