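## Protospacer/PAM scanning on both strands.
##
## Protospacer positions are numbered 1 (PAM-distal) to 20 (PAM-proximal);
## the PAM sits immediately 3' of position 20 on the guide strand.  NGG is a
## 3-nt PAM requiring G at PAM positions 2 and 3; NG is implemented as a
## 2-nt functional PAM requiring G at PAM position 2 only, so every NGG site
## is also an NG site.

PROTO_LEN <- 20L

#' Does a short sequence satisfy a PAM mode?
#'
#' @param bases PAM bases, 5' to 3' on the guide strand (>= 2 nt).
#' @param mode `"NGG"` or `"NG"`.
#' @return Logical.
#' @export
pam_match <- function(bases, mode = c("NGG", "NG")) {
  mode <- match.arg(mode)
  if (nchar(bases) < 2L) stop("PAM must be at least 2 nt")
  if (mode == "NGG") {
    nchar(bases) >= 3L && substr(bases, 2L, 2L) == "G" && substr(bases, 3L, 3L) == "G"
  } else {
    substr(bases, 2L, 2L) == "G"
  }
}

pam_width <- function(mode) if (mode == "NGG") 3L else 2L

#' Find all base-editor guide sites in a genome
#'
#' Enumerates every position, on both strands, where a 20-nt N-free
#' protospacer is followed 5' to 3' on its own strand by a PAM matching
#' `mode`.  Results are sorted by chromosome, then plus-strand start, then
#' strand (`+` before `-`).
#'
#' @param sequences A [genome_sequences] object.
#' @param mode PAM mode, `"NGG"` (default) or `"NG"`.
#' @param region Optional restriction, a list `list(chrom =, start =, end =)`
#'   with a 0-based half-open interval; only guides whose protospacer lies
#'   entirely inside the region are returned.
#' @return A data frame (class `guide_set`) with columns `guide_id`, `chrom`,
#'   `strand`, `start`, `end` (protospacer interval, 0-based half-open,
#'   plus-strand coordinates), `protospacer` (5'->3' on the guide strand) and
#'   `pam`.  The PAM mode is carried in attribute `pam_mode`.
#' @export
find_guides <- function(sequences, mode = c("NGG", "NG"), region = NULL) {
  mode <- match.arg(mode)
  pw <- pam_width(mode)
  out <- vector("list", 2L * length(sequences))
  k <- 0L
  for (chrom in names(sequences)) {
    seq <- sequences[[chrom]]
    L <- nchar(seq)
    if (L < PROTO_LEN + pw) next
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]

    ## plus strand: protospacer at 1-based a..a+19, PAM at a+20..a+19+pw.
    ## NGG needs ch[a+21]=='G' & ch[a+22]=='G'; NG needs ch[a+21]=='G'.
    a_max <- L - PROTO_LEN - pw + 1L
    if (a_max >= 1L) {
      a <- seq_len(a_max)
      keep <- ch[a + 21L] == "G"
      if (mode == "NGG") keep <- keep & ch[a + 22L] == "G"
      a <- a[keep]
      if (length(a)) {
        proto <- substring(seq, a, a + 19L)
        pam <- substring(seq, a + 20L, a + 19L + pw)
        ok <- !grepl("N", proto, fixed = TRUE) & !grepl("N", pam, fixed = TRUE)
        if (any(ok)) {
          k <- k + 1L
          out[[k]] <- data.frame(
            chrom = chrom, strand = "+",
            start = a[ok] - 1L, end = a[ok] + 19L,
            protospacer = proto[ok], pam = pam[ok],
            stringsAsFactors = FALSE)
        }
      }
    }

    ## minus strand: protospacer plus-interval a..a+19 (1-based); the guide
    ## reads the reverse complement; PAM occupies plus positions a-1..a-pw
    ## (pam position j at plus a-j).  NGG: ch[a-2]=='C' & ch[a-3]=='C'.
    a_min <- pw + 1L
    a_max <- L - PROTO_LEN + 1L
    if (a_max >= a_min) {
      a <- a_min:a_max
      keep <- ch[a - 2L] == "C"
      if (mode == "NGG") keep <- keep & ch[a - 3L] == "C"
      a <- a[keep]
      if (length(a)) {
        plus_proto <- substring(seq, a, a + 19L)
        plus_pam <- substring(seq, a - pw, a - 1L)
        ok <- !grepl("N", plus_proto, fixed = TRUE) & !grepl("N", plus_pam, fixed = TRUE)
        if (any(ok)) {
          a <- a[ok]
          k <- k + 1L
          out[[k]] <- data.frame(
            chrom = chrom, strand = "-",
            start = a - 1L, end = a + 19L,
            protospacer = vapply(plus_proto[ok], revcomp, character(1), USE.NAMES = FALSE),
            pam = vapply(plus_pam[ok], revcomp, character(1), USE.NAMES = FALSE),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  g <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               protospacer = character(0), pam = character(0),
               stringsAsFactors = FALSE)
  if (!is.null(region)) {
    g <- g[g$chrom == region$chrom & g$start >= region$start & g$end <= region$end, ,
           drop = FALSE]
  }
  g <- g[order(g$chrom, g$start, g$strand), , drop = FALSE]
  rownames(g) <- NULL
  g$guide_id <- sprintf("%s:%d-%d:%s", g$chrom, g$start, g$end, g$strand)
  g <- g[, c("guide_id", "chrom", "strand", "start", "end", "protospacer", "pam")]
  structure(g, class = c("guide_set", "data.frame"), pam_mode = mode)
}

#' Map a protospacer position to a genomic coordinate
#'
#' @param guide One row of a `guide_set` (or any list with `strand`, `start`,
#'   `end`).
#' @param p Protospacer position, 1 (PAM-distal) to 20 (PAM-proximal).
#' @return 0-based plus-strand genomic coordinate of the base the guide
#'   reads at position `p`.
#' @export
map_protospacer_pos <- function(guide, p) {
  if (any(p < 1L | p > PROTO_LEN)) stop("protospacer position out of range 1-20")
  if (guide$strand == "+") guide$start + (p - 1L) else guide$end - p
}

#' Write guide sites as BED6
#'
#' 0-based half-open intervals; the name column is the guide id, score the
#' protospacer position count of the PAM-proximal end (constant 0), strand
#' column used.
#'
#' @param guides A `guide_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_bed <- function(guides, path) {
  bed <- data.frame(guides$chrom, guides$start, guides$end,
                    guides$guide_id, 0L, guides$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
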