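## Synthetic test genomes with planted, manifest-tracked targetable sites,
## and an albA-like fixture gene embedding experimentally validated
## protospacers.
##
## Plant templates are written in coding-strand space and phase the codon
## boundaries, the protospacer and the PAM jointly, so every planted site is
## guaranteed discoverable under the default editing window (positions 4-8).
## Genes are placed on either genomic strand; minus-strand genes exercise
## the reverse-complement path of the scanner automatically.

## ---- deterministic Park-Miller generator (independent of R's RNG) --------

lcg_new <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- (as.numeric(seed) %% 2147483646) + 1
  e
}
lcg_next <- function(r) {
  r$state <- (16807 * r$state) %% 2147483647
  r$state
}
## integer in 0..(n-1)
lcg_int <- function(r, n) as.integer(lcg_next(r) %% n)
## integer in lo..hi
lcg_range <- function(r, lo, hi) lo + lcg_int(r, hi - lo + 1L)
lcg_pick <- function(r, xs) xs[lcg_int(r, length(xs)) + 1L]
## random DNA with a given GC fraction
lcg_dna <- function(r, len, gc = 0.5) {
  if (len <= 0L) return("")
  u <- vapply(seq_len(len), function(i) lcg_next(r) / 2147483647, numeric(1))
  b <- ifelse(u < gc / 2, "G", ifelse(u < gc, "C", ifelse(u < gc + (1 - gc) / 2, "A", "T")))
  paste(b, collapse = "")
}

SENSE_CODONS <- setdiff(
  as.vector(outer(as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)),
                  c("A", "C", "G", "T"), paste0)),
  c("TAA", "TAG", "TGA"))

lcg_codons <- function(r, n) vapply(seq_len(n), function(i) lcg_pick(r, SENSE_CODONS),
                                    character(1))

## ---- plant templates (coding-strand space) -------------------------------
##
## Each template returns codon overrides (by codon index), optionally an
## upstream-pad override (bases immediately 5' of the ATG), intron-head
## overrides, and the expected manifest record in CDS/intron offsets.

## CBE premature stop: CAG codon with its C at protospacer position 5 of a
## coding-strand guide, PAM 3' in the CDS.  Occupies 9 codons starting at
## `at`; the editable CAG sits at codon `at + 2`.
plant_stop_cbe <- function(at, pam) {
  codons <- c("GCT", "TTT", "CAG", "TTT", "TTT", "TTT", "TTT", "TTG",
              if (pam == "NGG") "GCA" else "TCA")
  list(codon_overrides = stats::setNames(as.list(codons), at + 0:8),
       upstream = NULL,
       manifest = list(strategy = "premature_stop", editor = "CBE",
                       codon_index = at + 2L, ref = "CAG", alt = "TAG",
                       cds_offset = 3L * (at + 1L)))   # 0-based offset of the C
}

## ABE start loss: coding-strand guide whose position 5 reads the A of ATG;
## needs the 4 bases 5' of the gene and codons 1-7.
plant_start_abe <- function(pam) {
  codons <- c("ATG", "TTT", "CTT", "TTC", "CTC", "GAG",
              if (pam == "NGG") "GAG" else "TTC")
  list(codon_overrides = stats::setNames(as.list(codons), 1:7),
       upstream = "CCTC",
       manifest = list(strategy = "start_loss", editor = "ABE",
                       codon_index = 1L, ref = "ATG", alt = "GTG",
                       cds_offset = 0L))
}

## CBE start loss: opposite-strand guide whose position 5 reads the G of ATG
## (as C); PAM lies 14-16 nt 5' of the gene.  Needs 16 upstream bases and
## codons 1-3.
plant_start_cbe <- function(pam) {
  up <- paste0(if (pam == "NGG") "C" else "T", "CT",
               paste(rep("T", 12), collapse = ""), "C")   # u16..u1
  list(codon_overrides = list(`1` = "ATG", `2` = "TTT", `3` = "TTC"),
       upstream = up,
       manifest = list(strategy = "start_loss", editor = "CBE",
                       codon_index = 1L, ref = "ATG", alt = "ATA",
                       cds_offset = 2L))
}

## ABE splice-donor disruption: opposite-strand guide whose position 5 reads
## the T of the intronic GT donor (as A); PAM sits in the upstream exon.
## Overrides the 6 exon codons preceding intron `intron_index` and the first
## 6 intron bases.
plant_splice_abe <- function(boundary_codon, intron_index, pam) {
  codons <- c(if (pam == "NGG") "TCC" else "TTC", "TTC", "TTC", "TTC", "TTC", "GCC")
  list(codon_overrides = stats::setNames(as.list(codons),
                                         boundary_codon - 5:0),
       intron_head = "GTATGC",
       intron_index = intron_index,
       manifest = list(strategy = "splice_disruption", editor = "ABE",
                       subsite = "donor", intron_index = intron_index,
                       intron_offset = 1L))   # 0-based offset of the donor T
}

## ---- gene cassette assembly ----------------------------------------------

## Build one gene in coding orientation.  `boundaries` are codon indices
## after which an intron is inserted; `introns` the intron sequences.
## Returns the cassette string plus exon/CDS offsets relative to the
## cassette (0-based half-open) and helpers to map CDS/intron offsets to
## cassette offsets.
build_cassette <- function(codons, boundaries, introns, upstream, downstream) {
  stopifnot(length(boundaries) == length(introns))
  cds <- paste(codons, collapse = "")
  n_nt <- nchar(cds)
  cuts <- c(0L, 3L * boundaries, n_nt)
  U <- nchar(upstream)
  pos <- U
  exons <- matrix(integer(0), ncol = 2L)
  intr_off <- integer(length(introns))
  pieces <- character(0)
  for (i in seq_len(length(cuts) - 1L)) {
    ex_seq <- substr(cds, cuts[i] + 1L, cuts[i + 1L])
    exons <- rbind(exons, c(pos, pos + nchar(ex_seq)))
    pieces <- c(pieces, ex_seq)
    pos <- pos + nchar(ex_seq)
    if (i <= length(introns)) {
      intr_off[i] <- pos
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  list(seq = paste0(upstream, paste(pieces, collapse = ""), downstream),
       exons = exons,                      # cassette offsets, coding orientation
       intron_offsets = intr_off,          # cassette offset of each intron start
       intron_lengths = nchar(introns),
       U = U,
       cds_to_cassette = function(off) {
         extra <- sum(nchar(introns)[3L * boundaries <= off])
         U + off + extra
       })
}

## random intron: GT ... AG, interior free
random_intron <- function(r, len, gc = 0.4) {
  stopifnot(len >= 4L)
  paste0("GT", lcg_dna(r, len - 4L, gc), "AG")
}

## cassette offset -> plus-strand genomic coordinate (0-based)
cassette_coord <- function(cass_start, cass_len, strand, off) {
  if (strand == "+") cass_start + off else cass_start + cass_len - 1L - off
}

## ---- synthetic genome spec + simulator -----------------------------------

#' Specification for a synthetic test genome
#'
#' @param n_genes Number of genes.
#' @param seed Integer seed (bit-reproducible output for a fixed seed).
#' @param gc GC fraction of intergenic and intron interior sequence.
#' @param codon_range Range of CDS lengths in codons (including the stop).
#' @param exon_range Range of exon counts per gene.
#' @param intron_range Range of intron lengths in nt.
#' @param intergenic_range Range of intergenic gap lengths in nt.
#' @param p_stop,p_start,p_splice Per-gene probability of planting a
#'   premature-stop, start-loss, or splice-donor target site.  Planted site
#'   PAMs are NGG or NG-only with equal probability; start plants use ABE or
#'   CBE chemistry with equal probability.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 100L, seed = 1L, gc = 0.45,
                           codon_range = c(80L, 200L),
                           exon_range = c(1L, 3L),
                           intron_range = c(50L, 70L),
                           intergenic_range = c(100L, 200L),
                           p_stop = 0.5, p_start = 0.5, p_splice = 0.5) {
  spec <- list(n_genes = as.integer(n_genes), seed = as.integer(seed), gc = gc,
               codon_range = as.integer(codon_range),
               exon_range = as.integer(exon_range),
               intron_range = as.integer(intron_range),
               intergenic_range = as.integer(intergenic_range),
               p_stop = p_stop, p_start = p_start, p_splice = p_splice)
  if (spec$codon_range[1] < 45L) {
    stop("codon_range minimum must be >= 45 (room for planted sites and the 5' quarter rule)")
  }
  if (spec$intron_range[1] < 10L) stop("intron_range minimum must be >= 10")
  structure(spec, class = "synthetic_spec")
}

#' Simulate a genome with planted base-editing target sites
#'
#' Generates a single-chromosome genome of `n_genes` genes on both strands
#' with valid `ATG ... stop` coding sequences and `GT ... AG` introns.
#' Depending on the per-strategy probabilities, each gene receives planted
#' target sites guaranteed editable under the default window (protospacer
#' positions 4-8); every plant is recorded in a truth manifest with its
#' expected classification and genomic coordinate.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_genome`: `sequences`
#'   ([genome_sequences]), `models` (`gene_model_list`), and `manifest`
#'   (data frame: `gene_id`, `strategy`, `editor`, `pam`, `chrom`, `coord`
#'   0-based, `ref`, `alt`, `codon_index`, `intron_index`, `subsite`).
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  r <- lcg_new(spec$seed)
  chrom <- "chr1"
  parts <- character(0)
  pos <- 0L
  models <- list()
  manifest <- list()

  add_part <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }

  for (gi in seq_len(spec$n_genes)) {
    gene_id <- sprintf("g%03d", gi)
    add_part(lcg_dna(r, lcg_range(r, spec$intergenic_range[1], spec$intergenic_range[2]),
                     spec$gc))
    strand <- if (lcg_int(r, 2L) == 0L) "+" else "-"
    n_codons <- lcg_range(r, spec$codon_range[1], spec$codon_range[2])

    want_splice <- lcg_next(r) / 2147483647 < spec$p_splice
    n_exons <- lcg_range(r, spec$exon_range[1], spec$exon_range[2])
    if (want_splice && n_exons < 2L) n_exons <- 2L

    boundaries <- integer(0)
    if (n_exons >= 2L) {
      ## first boundary >= 24 so a splice plant (6 codons before the intron)
      ## can never collide with the stop plant block at codons 9-17
      b1 <- lcg_range(r, 24L, min(40L, n_codons - 25L))
      boundaries <- b1
      if (n_exons == 3L) boundaries <- c(b1, lcg_range(r, b1 + 15L, n_codons - 20L))
    }
    introns <- vapply(seq_along(boundaries), function(i) {
      random_intron(r, lcg_range(r, spec$intron_range[1], spec$intron_range[2]), spec$gc)
    }, character(1))

    codons <- c("ATG", lcg_codons(r, n_codons - 2L), lcg_pick(r, c("TAA", "TAG", "TGA")))
    upstream <- lcg_dna(r, 30L, spec$gc)
    downstream <- lcg_dna(r, 20L, spec$gc)

    plants <- list()
    if (lcg_next(r) / 2147483647 < spec$p_stop) {
      plants[[length(plants) + 1L]] <- plant_stop_cbe(9L, lcg_pick(r, PAMS))
    }
    if (lcg_next(r) / 2147483647 < spec$p_start) {
      pam <- lcg_pick(r, PAMS)
      plants[[length(plants) + 1L]] <-
        if (lcg_int(r, 2L) == 0L) plant_start_abe(pam) else plant_start_cbe(pam)
      plants[[length(plants)]]$pam <- pam
    }
    if (want_splice) {
      plants[[length(plants) + 1L]] <- plant_splice_abe(boundaries[1], 1L,
                                                        lcg_pick(r, PAMS))
    }
    ## record pam chosen inside templates that took it as an argument
    for (k in seq_along(plants)) {
      if (is.null(plants[[k]]$pam)) {
        ov <- plants[[k]]$codon_overrides
        plants[[k]]$pam <- infer_plant_pam(plants[[k]], ov)
      }
    }

    for (pl in plants) {
      for (ci in names(pl$codon_overrides)) {
        codons[as.integer(ci)] <- pl$codon_overrides[[ci]]
      }
      if (!is.null(pl$upstream)) {
        substr(upstream, 31L - nchar(pl$upstream), 30L) <- pl$upstream
      }
      if (!is.null(pl$intron_head)) {
        substr(introns[pl$intron_index], 1L, nchar(pl$intron_head)) <- pl$intron_head
      }
    }

    cass <- build_cassette(codons, boundaries, introns, upstream, downstream)
    L <- nchar(cass$seq)
    cass_seq <- if (strand == "+") cass$seq else revcomp(cass$seq)
    cass_start <- pos
    add_part(cass_seq)

    ## genomic exon intervals
    ex <- cass$exons
    gex <- if (strand == "+") {
      cbind(cass_start + ex[, 1L], cass_start + ex[, 2L])
    } else {
      m <- cbind(cass_start + L - ex[, 2L], cass_start + L - ex[, 1L])
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    }
    models[[length(models) + 1L]] <- list(
      gene_id = gene_id, strand = strand, exons = gex)

    for (pl in plants) {
      mf <- pl$manifest
      off <- if (mf$strategy == "splice_disruption") {
        cass$intron_offsets[mf$intron_index] + mf$intron_offset
      } else {
        cass$cds_to_cassette(mf$cds_offset)
      }
      manifest[[length(manifest) + 1L]] <- data.frame(
        gene_id = gene_id, strategy = mf$strategy, editor = mf$editor,
        pam = pl$pam, chrom = chrom,
        coord = cassette_coord(cass_start, L, strand, off),
        ref = if (is.null(mf$ref)) NA_character_ else mf$ref,
        alt = if (is.null(mf$alt)) NA_character_ else mf$alt,
        codon_index = if (is.null(mf$codon_index)) NA_integer_ else mf$codon_index,
        intron_index = if (is.null(mf$intron_index)) NA_integer_ else mf$intron_index,
        subsite = if (is.null(mf$subsite)) NA_character_ else mf$subsite,
        stringsAsFactors = FALSE)
    }
  }
  add_part(lcg_dna(r, lcg_range(r, spec$intergenic_range[1], spec$intergenic_range[2]),
                   spec$gc))

  sequences <- genome_sequences(stats::setNames(paste(parts, collapse = ""), chrom))
  gml <- lapply(models, function(m) {
    build_gene_model(gene_id = m$gene_id, mrna_id = paste0(m$gene_id, ".t1"),
                     chrom = chrom, strand = m$strand,
                     exons = m$exons, cds = m$exons, sequences = sequences)
  })
  class(gml) <- "gene_model_list"
  bad <- vapply(gml, function(m) !m$complete, logical(1))
  if (any(bad)) {
    stop("synthetic generator produced incomplete models: ",
         paste(vapply(gml[bad], `[[`, character(1), "gene_id"), collapse = ", "))
  }
  mf <- if (length(manifest)) do.call(rbind, manifest) else data.frame()
  structure(list(sequences = sequences, models = gml, manifest = mf, spec = spec),
            class = "synthetic_genome")
}

## a template that did not receive pam explicitly stores it implicitly in its
## last PAM-bearing codon; stop template: codon 9 of the block
infer_plant_pam <- function(plant, overrides) {
  if (plant$manifest$strategy == "premature_stop") {
    last <- overrides[[length(overrides)]]
    if (last == "GCA") "NGG" else "NG"
  } else if (plant$manifest$strategy == "splice_disruption") {
    if (overrides[[1L]] == "TCC") "NGG" else "NG"
  } else stop("plant missing pam")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("synthetic_genome: %d gene(s), %d planted site(s), %s bp (seed %d)\n",
              length(x$models), nrow(x$manifest),
              format(nchar(x$sequences[[1]]), big.mark = ","), x$spec$seed))
  invisible(x)
}

## ---- albA-like fixture ----------------------------------------------------

ALBA_TS1 <- "CGCTGACCAGCATGTTGACT"   # CBE, opposite-strand guide over codon 55 (TGG)
ALBA_TS2 <- "ACGACGACTATGCTGGGACA"   # CBE, coding-strand guide over codon 292 (CGA)

#' An albA-like five-exon fixture gene
#'
#' A synthetic 600-codon, five-exon gene built so that (i) the two
#' experimentally validated CBE protospacers sit in their native
#' configuration -- `CGCTGACCAGCATGTTGACT` as an opposite-strand NGG guide
#' whose window covers the Gs of the tryptophan codon at position 55
#' (TGG -> TAG/TGA), and `ACGACGACTATGCTGGGACA` as a coding-strand NGG guide
#' whose window covers the arginine codon CGA at position 292 (-> TGA);
#' (ii) intron 2 carries an ABE-editable splice-donor site; and (iii) the
#' start codon is covered by an NG-only ABE site (no NGG guide can reach
#' it).  Intron lengths mix in-frame (57, 60) and frameshifting (64, 58)
#' cases.  The real albA genomic sequence is not public in printed form;
#' this fixture is synthetic but reproduces the documented site geometry,
#' and is verified by a self-check at build time.
#'
#' @param check Run the build-time self-check (default `TRUE`).
#' @return A list: `sequences`, `models` (one gene, `albA`), and `sites`
#'   (the expected landmark candidates).
#' @export
alba_fixture <- function(check = TRUE) {
  r <- lcg_new(20260921L)
  n <- 600L
  codons <- c("ATG", lcg_codons(r, n - 2L), "TAA")

  ## NG-only ABE start site: codons 1-7 + the 4 bases 5' of the ATG
  st <- plant_start_abe("NG")
  for (ci in names(st$codon_overrides)) codons[as.integer(ci)] <- st$codon_overrides[[ci]]

  ## codon 55 = TGG read by ALBA_TS1 on the opposite strand:
  ## coding strand carries revcomp(TS1) at CDS nt 152-171 with a CC PAM
  ## context at nt 149-150; codons 50-57 are forced accordingly.
  rc1 <- revcomp(ALBA_TS1)                     # AGTCAACATGCTGGTCAGCG
  codons[50L] <- "TCC"
  codons[51L] <- paste0("G", substr(rc1, 1L, 2L))
  for (k in 0:5) codons[52L + k] <- substr(rc1, 3L + 3L * k, 5L + 3L * k)
  stopifnot(codons[55L] == "TGG")

  ## codon 292 = CGA read by ALBA_TS2 on the coding strand (TS2 spans CDS nt
  ## 870-889, NGG PAM at nt 890-892); codons 290-298 forced.
  codons[290L] <- paste0("GC", substr(ALBA_TS2, 1L, 1L))
  for (k in 0:5) codons[291L + k] <- substr(ALBA_TS2, 2L + 3L * k, 4L + 3L * k)
  codons[297L] <- paste0(substr(ALBA_TS2, 20L, 20L), "TG")
  codons[298L] <- "GCT"
  stopifnot(codons[292L] == "CGA")

  ## five exons; introns after codons 45, 150, 300, 450
  boundaries <- c(45L, 150L, 300L, 450L)
  introns <- c(random_intron(r, 57L),    # in frame
               random_intron(r, 64L),    # frameshifting; carries the donor plant
               random_intron(r, 58L),
               random_intron(r, 60L))

  ## ABE splice-donor site at intron 2
  sp <- plant_splice_abe(150L, 2L, "NGG")
  for (ci in names(sp$codon_overrides)) codons[as.integer(ci)] <- sp$codon_overrides[[ci]]
  substr(introns[2L], 1L, nchar(sp$intron_head)) <- sp$intron_head

  ## fixed AT-rich promoter tail: keeps the 20 bases 5' of the ATG free of
  ## CC/GG pairs so no NGG guide can reach the start codon (the site must be
  ## NG-only), while ending in the non-A base the ABE plant requires at
  ## protospacer position 4
  upstream <- lcg_dna(r, 200L, 0.35)
  substr(upstream, 181L, 200L) <- "TATTTATTTATTTATTTTTC"
  downstream <- lcg_dna(r, 200L, 0.35)

  cass <- build_cassette(codons, boundaries, introns, upstream, downstream)
  sequences <- genome_sequences(c(chr_albA = cass$seq))
  model <- build_gene_model(gene_id = "albA", mrna_id = "albA.t1",
                            chrom = "chr_albA", strand = "+",
                            exons = cass$exons, cds = cass$exons,
                            sequences = sequences)
  models <- structure(list(model), class = "gene_model_list")
  stopifnot(model$complete)

  if (check) {
    cand_ngg <- design_candidates(sequences, models, pam = "NGG")
    stops <- cand_ngg[cand_ngg$strategy == "premature_stop" & cand_ngg$editor == "CBE", ]
    stopifnot(any(stops$codon_index == 55L & stops$alt_codon == "TAG"),
              any(stops$codon_index == 292L & stops$alt_codon == "TGA"))
    spl <- cand_ngg[cand_ngg$strategy == "splice_disruption" & cand_ngg$editor == "ABE", ]
    stopifnot(any(spl$intron_index == 2L & spl$subsite == "donor"))
    starts_ngg <- cand_ngg[cand_ngg$strategy == "start_loss", ]
    cand_ng <- design_candidates(sequences, models, pam = "NG")
    starts_ng <- cand_ng[cand_ng$strategy == "start_loss" & cand_ng$editor == "ABE", ]
    stopifnot(nrow(starts_ngg) == 0L, any(starts_ng$alt_codon == "GTG"))
  }

  list(sequences = sequences, models = models,
       sites = data.frame(
         strategy = c("premature_stop", "premature_stop", "splice_disruption",
                      "start_loss"),
         editor = c("CBE", "CBE", "ABE", "ABE"),
         pam = c("NGG", "NGG", "NGG", "NG"),
         codon_index = c(55L, 292L, NA, 1L),
         ref = c("TGG", "CGA", NA, "ATG"),
         alt = c("TAG", "TGA", NA, "GTG"),
         intron_index = c(NA, NA, 2L, NA),
         stringsAsFactors = FALSE))
}
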