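## Genome and annotation input: FASTA sequences, GFF3 gene models, and the
## small sequence utilities everything downstream rests on.
##
## Internal coordinate convention (used by every module): 0-based half-open
## intervals on the plus strand.  GFF3 is converted on read (internal_start =
## gff_start - 1, internal_end = gff_end) and back on write.

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a genome FASTA file
#'
#' Loads all records of a FASTA file into a named character vector of
#' uppercase sequences.  Multi-line records are concatenated and case is
#' folded to upper.  Any residue outside `A/C/G/T/N` is a hard error naming
#' the record and offset; duplicate record names are a hard error.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector (class `genome_sequences`); names are the
#'   FASTA record identifiers (first whitespace-delimited token).
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(genome_sequences(character(0)))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_sequences(seqs)
}

#' Construct a validated genome sequence set
#'
#' @param seqs Named character vector of DNA sequences.
#' @return The uppercased, validated vector with class `genome_sequences`.
#' @export
genome_sequences <- function(seqs) {
  seqs <- toupper(seqs)
  if (anyDuplicated(names(seqs))) {
    stop("duplicate sequence name: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  for (nm in names(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[nm]])
    if (bad != -1L) {
      stop(sprintf("illegal residue '%s' in record '%s' at position %d",
                   substr(seqs[[nm]], bad, bad), nm, as.integer(bad)))
    }
  }
  structure(seqs, class = "genome_sequences")
}

#' @export
print.genome_sequences <- function(x, ...) {
  cat(sprintf("genome_sequences: %d sequence(s), %s bp total\n",
              length(x), format(sum(nchar(x)), big.mark = ",")))
  for (nm in names(x)) cat(sprintf("  %s  %d bp\n", nm, nchar(x[[nm]])))
  invisible(x)
}

#' Reverse complement of a DNA string
#'
#' `N` maps to `N`; any other residue outside `A/C/G/T` is an error.
#'
#' @param seq A DNA string over `A/C/G/T/N`.
#' @return The reverse complement, same alphabet.
#' @export
revcomp <- function(seq) {
  if (grepl("[^ACGTN]", seq)) stop("illegal residue in sequence")
  ch <- chartr("ACGTN", "TGCAN", seq)
  paste(rev(strsplit(ch, "", fixed = TRUE)[[1]]), collapse = "")
}

## complement of a character vector of single bases
comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

## 0-based half-open slice of a plain character sequence
seq_slice <- function(seq, start0, end0) substr(seq, start0 + 1L, end0)

#' Read gene models from GFF3
#'
#' Parses a GFF3 annotation (gene -> mRNA -> exon/CDS) into one gene model
#' per gene.  When a gene carries several mRNAs the mRNA with the longest
#' total CDS is kept (ties broken by lexicographically smallest mRNA ID).
#' Coordinates are converted from the 1-based inclusive GFF3 dialect to the
#' internal 0-based half-open convention.
#'
#' Models that are structurally incomplete -- CDS length not a multiple of
#' three, spliced CDS not starting `ATG` or not ending in a stop, internal
#' stop codons, `N` residues in the CDS, or an intron shorter than 4 nt --
#' are flagged (`complete = FALSE`, with a reason) rather than errored, and
#' are excluded from genome summaries.
#'
#' @param path Path to a GFF3 file.
#' @param sequences A [genome_sequences] object (used for bounds checking and
#'   CDS validation).
#' @return A list of gene models (class `gene_model_list`).  Each element is
#'   a list with `gene_id`, `mrna_id`, `chrom`, `strand`, `exons`, `cds`
#'   (two-column matrices of 0-based half-open intervals sorted by genomic
#'   position), `introns`, `start_codon`, `cds_length`, `n_codons`,
#'   `complete`, `flag`.
#' @export
read_gff <- function(path, sequences) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$Parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                      character(1))
  df$type <- as.character(df$type)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS", , drop = FALSE]

  orphan <- !(cdss$Parent %in% mrnas$ID)
  if (any(orphan)) {
    warning(sum(orphan), " CDS feature(s) without a parent mRNA skipped")
    cdss <- cdss[!orphan, , drop = FALSE]
  }

  models <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gm <- mrnas[mrnas$Parent == g$ID, , drop = FALSE]
    if (nrow(gm) == 0L) next
    ## longest-total-CDS transcript; ties -> smallest mRNA ID
    cds_tot <- vapply(gm$ID, function(m) {
      seg <- cdss[cdss$Parent == m, , drop = FALSE]
      if (nrow(seg) == 0L) 0L else sum(seg$end - seg$start + 1L)
    }, integer(1))
    ord <- order(-cds_tot, gm$ID)
    mid <- gm$ID[ord[1]]

    ex <- exons[exons$Parent == mid, , drop = FALSE]
    cd <- cdss[cdss$Parent == mid, , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cd   # exon features optional when CDS given
    chrom <- g$seqnames
    if (!chrom %in% names(sequences)) {
      stop("gene ", g$ID, " on unknown sequence ", chrom)
    }
    clen <- nchar(sequences[[chrom]])
    if (any(ex$end > clen) || any(cd$end > clen)) {
      stop("feature beyond end of sequence ", chrom, " for gene ", g$ID)
    }
    models[[i]] <- build_gene_model(
      gene_id = g$ID,
      mrna_id = mid,
      chrom = chrom,
      strand = g$strand,
      exons = cbind(ex$start - 1L, ex$end)[order(ex$start), , drop = FALSE],
      cds   = cbind(cd$start - 1L, cd$end)[order(cd$start), , drop = FALSE],
      sequences = sequences
    )
  }
  models <- models[!vapply(models, is.null, logical(1))]
  structure(models, class = "gene_model_list")
}

## Assemble and validate one gene model from 0-based half-open intervals.
build_gene_model <- function(gene_id, mrna_id, chrom, strand, exons, cds,
                             sequences) {
  storage.mode(exons) <- "integer"
  storage.mode(cds) <- "integer"
  n_ex <- nrow(exons)
  introns <- if (n_ex > 1L) {
    cbind(exons[-n_ex, 2L], exons[-1L, 1L])
  } else {
    matrix(integer(0), ncol = 2L)
  }
  storage.mode(introns) <- "integer"

  cds_len <- sum(cds[, 2L] - cds[, 1L])
  flag <- character(0)
  if (n_ex > 1L && any(introns[, 2L] - introns[, 1L] < 4L)) {
    flag <- c(flag, "intron_too_short")
  }
  if (any(exons[, 1L] >= exons[, 2L])) flag <- c(flag, "empty_exon")
  if (n_ex > 1L && any(exons[-1L, 1L] < exons[-n_ex, 2L])) {
    flag <- c(flag, "overlapping_exons")
  }

  ## start codon: first CDS codon in transcription order
  start_codon <- if (strand == "+") {
    c(cds[1L, 1L], cds[1L, 1L] + 3L)
  } else {
    c(cds[nrow(cds), 2L] - 3L, cds[nrow(cds), 2L])
  }

  model <- list(
    gene_id = gene_id, mrna_id = mrna_id, chrom = chrom, strand = strand,
    exons = exons, cds = cds, introns = introns,
    start_codon = as.integer(start_codon),
    cds_length = as.integer(cds_len),
    n_codons = as.integer(cds_len %/% 3L),
    complete = TRUE, flag = ""
  )
  class(model) <- "gene_model"

  if (cds_len %% 3L != 0L) flag <- c(flag, "cds_not_multiple_of_3")
  if (length(flag) == 0L) {
    cds_seq <- spliced_cds(model, sequences, check = FALSE)
    if (grepl("N", cds_seq, fixed = TRUE)) {
      flag <- c(flag, "cds_contains_N")
    } else {
      aa <- translate_dna(cds_seq)
      if (substr(cds_seq, 1L, 3L) != "ATG") flag <- c(flag, "non_ATG_start")
      if (substr(aa, nchar(aa), nchar(aa)) != "*") flag <- c(flag, "no_terminal_stop")
      if (grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE)) {
        flag <- c(flag, "internal_stop")
      }
    }
  }
  if (length(flag)) {
    model$complete <- FALSE
    model$flag <- paste(flag, collapse = ",")
  }
  model
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s:%s) %d exon(s), CDS %d nt (%d codons)%s\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons), x$cds_length,
              x$n_codons, if (x$complete) "" else paste0(" [", x$flag, "]")))
  invisible(x)
}

#' @export
print.gene_model_list <- function(x, ...) {
  cat(sprintf("gene_model_list: %d gene(s), %d complete\n",
              length(x), sum(vapply(x, `[[`, logical(1), "complete"))))
  invisible(x)
}

#' Spliced coding sequence of a gene
#'
#' Concatenates the CDS segments in transcription order; minus-strand genes
#' are reverse-complemented so the result always reads 5' to 3' on the
#' coding strand, beginning at the start codon.
#'
#' @param gene A gene model from [read_gff()].
#' @param sequences The [genome_sequences] the model refers to.
#' @param check If `TRUE` (default) require a complete model.
#' @return The spliced CDS as a character string.
#' @export
spliced_cds <- function(gene, sequences, check = TRUE) {
  if (check && !gene$complete) {
    stop("gene ", gene$gene_id, " is flagged incomplete (", gene$flag, ")")
  }
  chrom_seq <- sequences[[gene$chrom]]
  parts <- vapply(seq_len(nrow(gene$cds)), function(i) {
    seq_slice(chrom_seq, gene$cds[i, 1L], gene$cds[i, 2L])
  }, character(1))
  s <- paste(parts, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

## DNA -> protein ('*' = stop), standard code.  Trailing partial codon dropped.
translate_dna <- function(dna) {
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  codons <- substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## 1-based coding-strand CDS position of a genomic coordinate (0-based),
## or NA if the coordinate is not inside the CDS.
cds_position <- function(gene, gcoord) {
  cds <- gene$cds
  hit <- which(gcoord >= cds[, 1L] & gcoord < cds[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  if (gene$strand == "+") {
    before <- if (hit > 1L) sum(cds[seq_len(hit - 1L), 2L] - cds[seq_len(hit - 1L), 1L]) else 0L
    as.integer(before + (gcoord - cds[hit, 1L]) + 1L)
  } else {
    n <- nrow(cds)
    after <- if (hit < n) sum(cds[(hit + 1L):n, 2L] - cds[(hit + 1L):n, 1L]) else 0L
    as.integer(after + (cds[hit, 2L] - 1L - gcoord) + 1L)
  }
}

## index of the intron (transcription order) containing a genomic coordinate,
## or NA.  Also returns the 1-based offset within the intron on the coding
## strand via attribute "offset".
intron_position <- function(gene, gcoord) {
  intr <- gene$introns
  if (nrow(intr) == 0L) return(NA_integer_)
  hit <- which(gcoord >= intr[, 1L] & gcoord < intr[, 2L])
  if (length(hit) == 0L) return(NA_integer_)
  n <- nrow(intr)
  if (gene$strand == "+") {
    idx <- hit
    off <- gcoord - intr[hit, 1L] + 1L
  } else {
    idx <- n - hit + 1L
    off <- intr[hit, 2L] - gcoord
  }
  structure(as.integer(idx), offset = as.integer(off))
}

## intron sequence on the coding strand, by transcription-order index
intron_seq <- function(gene, index, sequences) {
  intr <- gene$introns
  if (index < 1L || index > nrow(intr)) stop("intron index out of range")
  row <- if (gene$strand == "+") index else nrow(intr) - index + 1L
  s <- seq_slice(sequences[[gene$chrom]], intr[row, 1L], intr[row, 2L])
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Write gene models to GFF3
#'
#' Emits gene / mRNA / exon / CDS features in the standard 1-based inclusive
#' GFF3 dialect.  Re-reading the file with [read_gff()] reproduces the models.
#'
#' @param models A `gene_model_list`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(min(m$exons[, 1L], m$cds[, 1L]), max(m$exons[, 2L], m$cds[, 2L]))
    gid <- m$gene_id
    mid <- m$mrna_id
    lines <- c(lines,
      sprintf("%s\tbescan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              m$chrom, span[1L] + 1L, span[2L], m$strand, gid),
      sprintf("%s\tbescan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              m$chrom, span[1L] + 1L, span[2L], m$strand, mid, gid))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, sprintf(
        "%s\tbescan\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        m$chrom, m$exons[i, 1L] + 1L, m$exons[i, 2L], m$strand, mid, i, mid))
    }
    for (i in seq_len(nrow(m$cds))) {
      lines <- c(lines, sprintf(
        "%s\tbescan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
        m$chrom, m$cds[i, 1L] + 1L, m$cds[i, 2L], m$strand, mid, i, mid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param sequences A [genome_sequences] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(unclass(sequences))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
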