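# The albA-like fixture carries the validated site geometry: a tryptophan
# codon at position 55 reachable by an opposite-strand CBE guide, an
# arginine CGA codon at position 292 under a coding-strand CBE guide, an
# ABE-editable donor in intron 2, and an NG-only start-codon site.

fixture <- alba_fixture()

test_that("CBE finds the codon-55 and codon-292 nonsense candidates", {
  cand <- design_candidates(fixture$sequences, fixture$models,
                            editors = "CBE", pam = "NGG")
  stops <- cand[cand$strategy == "premature_stop", ]
  expect_true(any(stops$codon_index == 55 & stops$ref_codon == "TGG" &
                  stops$alt_codon == "TAG"))
  expect_true(any(stops$codon_index == 55 & stops$alt_codon == "TGA"))
  expect_true(any(stops$codon_index == 292 & stops$ref_codon == "CGA" &
                  stops$alt_codon == "TGA"))
  # 5' quarter of 600 codons ends at codon 150
  expect_true(all(stops$within_quarter[stops$codon_index == 55]))
  expect_false(any(stops$within_quarter[stops$codon_index == 292]))
})

test_that("ABE yields no premature-stop candidates anywhere", {
  cand <- design_candidates(fixture$sequences, fixture$models,
                            editors = "ABE", pam = "NG")
  expect_equal(sum(cand$strategy == "premature_stop"), 0L)
  sim <- simulate_genome(synthetic_spec(n_genes = 10, seed = 17))
  cand <- design_candidates(sim$sequences, sim$models, editors = "ABE",
                            pam = "NG")
  expect_equal(sum(cand$strategy == "premature_stop"), 0L)
})

test_that("start-codon candidates follow the editor chemistry", {
  # ABE position 1 on the fixture: ATG -> GTG, NG-only
  ngg <- design_candidates(fixture$sequences, fixture$models, pam = "NGG")
  expect_equal(sum(ngg$strategy == "start_loss"), 0L)
  ng <- design_candidates(fixture$sequences, fixture$models, pam = "NG")
  starts <- ng[ng$strategy == "start_loss", ]
  expect_true(any(starts$editor == "ABE" & starts$alt_codon == "GTG"))

  # ABE position 2 via an opposite-strand guide: ATG -> ACG
  up <- "CCTTTTTTTTTTTTTCC"          # places an AGG PAM 15-17 nt 5' of the ATG
  cds <- paste0("ATG", strrep("TTT", 20), "TAA")
  chrom <- paste0("GCGC", up, cds, "GCGC")
  f <- toy_gene_files(chrom, exons = rbind(c(21, 21 + nchar(cds))))
  seqs <- read_fasta(f$fa); models <- read_gff(f$gff, seqs)
  cand <- design_candidates(seqs, models, editors = "ABE", pam = "NGG")
  starts <- cand[cand$strategy == "start_loss", ]
  expect_true(any(starts$alt_codon == "ACG"))

  # CBE position 3 via an opposite-strand guide: ATG -> ATA
  up <- "CCTTTTTTTTTTTTTC"           # 16 nt: CC PAM context 14-16 nt upstream
  chrom <- paste0("GCGC", up, cds, "GCGC")
  f <- toy_gene_files(chrom, exons = rbind(c(20, 20 + nchar(cds))))
  seqs <- read_fasta(f$fa); models <- read_gff(f$gff, seqs)
  cand <- design_candidates(seqs, models, editors = "CBE", pam = "NGG")
  starts <- cand[cand$strategy == "start_loss", ]
  expect_true(any(starts$alt_codon == "ATA"))
})

test_that("splice candidates classify donor/acceptor/branch subsites", {
  cand <- design_candidates(fixture$sequences, fixture$models, pam = "NGG")
  spl <- cand[cand$strategy == "splice_disruption", ]
  donor2 <- spl[spl$intron_index == 2 & spl$subsite == "donor", ]
  expect_gte(nrow(donor2), 1L)
  expect_true(any(donor2$editor == "ABE"))   # the planted GT>GC donor edit
  # donor/acceptor are tier 1, everything else tier 2
  expect_true(all(spl$tier[spl$subsite %in% c("donor", "acceptor")] == 1L))
  expect_true(all(spl$tier[!spl$subsite %in% c("donor", "acceptor")] == 2L))
  # every splice candidate lies inside an intron of its gene
  intr <- fixture$models[[1]]$introns
  inside <- vapply(spl$gcoord, function(x) any(x >= intr[, 1] & x < intr[, 2]),
                   logical(1))
  expect_true(all(inside))

  # an intronless gene yields no splice candidates
  chrom <- paste0("GCGC", "ATG", strrep("GCT", 30), "TAA", "GCGC")
  f <- toy_gene_files(chrom, exons = rbind(c(4, 4 + 96)))
  seqs <- read_fasta(f$fa); models <- read_gff(f$gff, seqs)
  cand <- design_candidates(seqs, models, pam = "NG")
  expect_equal(sum(cand$strategy == "splice_disruption"), 0L)
})

test_that("an ABE acceptor edit is classified at the intron's terminal AG", {
  exon1 <- paste0("ATG", strrep("GCT", 10))
  intron <- paste0("GT", strrep("T", 20), "TAG")   # 25 nt, ends ...T A G
  exon2 <- paste0(strrep("T", 15), "GGT", strrep("GCT", 8), "TAA")
  chrom <- paste0("GCGC", exon1, intron, exon2, "GCGC")
  e1 <- c(4, 4 + nchar(exon1))
  e2 <- c(e1[2] + nchar(intron), e1[2] + nchar(intron) + nchar(exon2))
  f <- toy_gene_files(chrom, exons = rbind(e1, e2))
  seqs <- read_fasta(f$fa); models <- read_gff(f$gff, seqs)
  expect_true(models[[1]]$complete)
  cand <- design_candidates(seqs, models, editors = "ABE", pam = "NGG")
  acc <- cand[cand$strategy == "splice_disruption" & cand$subsite == "acceptor", ]
  expect_gte(nrow(acc), 1L)
  # the edited base is the A of the terminal AG
  expect_true(any(acc$gcoord == e2[1] - 2))
})

test_that("intron retention reports frame and premature stops correctly", {
  gene <- fixture$models[[1]]
  r1 <- simulate_intron_retention(gene, 1, fixture$sequences)
  expect_false(r1$frameshift)            # 57-nt intron keeps the frame
  r2 <- simulate_intron_retention(gene, 2, fixture$sequences)
  expect_true(r2$frameshift)             # 64-nt intron shifts it
  expect_error(simulate_intron_retention(gene, 9, fixture$sequences),
               "out of range")

  # hand-built 9-nt in-frame intron carrying TAA in frame:
  # ATG AAA | GTATAACAG | TTT TAA  -> retained: ATG AAA GTA TAA ...
  chrom <- paste0("CC", "ATGAAA", "GTATAACAG", "TTTTAA", "CC")
  f <- toy_gene_files(chrom, exons = rbind(c(2, 8), c(17, 23)))
  seqs <- read_fasta(f$fa); m <- read_gff(f$gff, seqs)[[1]]
  expect_true(m$complete)
  r <- simulate_intron_retention(m, 1, seqs)
  expect_false(r$frameshift)
  expect_equal(r$ptc_codon, 4L)
  expect_equal(r$truncated_length, 3L)

  # retention is invariant under mirroring the locus to the other strand
  mir <- mirror_genome(list(sequences = fixture$sequences,
                            models = fixture$models))
  for (ix in 1:4) {
    a <- simulate_intron_retention(gene, ix, fixture$sequences)
    b <- simulate_intron_retention(mir$models[[1]], ix, mir$sequences)
    expect_equal(a[c("frameshift", "ptc_codon", "intron_length")],
                 b[c("frameshift", "ptc_codon", "intron_length")])
  }
})

test_that("consequences follow the strategy semantics", {
  cand <- design_candidates(fixture$sequences, fixture$models, pam = "NG")
  c55 <- cand[cand$strategy == "premature_stop" & cand$codon_index == 55 &
              cand$alt_codon == "TAG", ][1, ]
  q <- predict_consequence(fixture$models[[1]], c55, fixture$sequences)
  expect_equal(q$kind, "nonsense")
  expect_equal(q$truncated_length, 54L)

  spl <- cand[cand$strategy == "splice_disruption" & cand$intron_index == 2, ][1, ]
  q <- predict_consequence(fixture$models[[1]], spl, fixture$sequences)
  expect_equal(q$kind, "intron_retention")
  expect_equal(q$intron_index, 2L)
  expect_true(q$frameshift)

  # start loss reports the next in-frame ATG (planted at codon 12)
  up <- "CCTTTTTTTTTTTTTCC"
  codons <- c("ATG", rep("TTT", 9), "TTT", "ATG", rep("GCT", 8), "TAA")
  cds <- paste(codons, collapse = "")
  chrom <- paste0("GCGC", up, cds, "GCGC")
  f <- toy_gene_files(chrom, exons = rbind(c(21, 21 + nchar(cds))))
  seqs <- read_fasta(f$fa); models <- read_gff(f$gff, seqs)
  cand <- design_candidates(seqs, models, editors = "ABE", pam = "NGG")
  st <- cand[cand$strategy == "start_loss", ][1, ]
  q <- predict_consequence(models[[1]], st, seqs)
  expect_equal(q$kind, "start_loss")
  expect_equal(q$next_inframe_atg, 12L)
})

test_that("applying a stop edit re-translates with the stop at the reported codon", {
  check_stop_edits <- function(sequences, models, pam) {
    cand <- design_candidates(sequences, models, pam = pam)
    stops <- cand[cand$strategy == "premature_stop", ]
    models_by_id <- stats::setNames(models, vapply(models, `[[`, "", "gene_id"))
    for (i in seq_len(nrow(stops))) {
      cd <- stops[i, ]
      mut <- apply_edit(sequences, as.list(cd))
      gene <- models_by_id[[cd$gene_id]]
      aa <- oracle_translate(spliced_cds(gene, mut))
      first <- regexpr("*", aa, fixed = TRUE)
      expect_equal(as.integer(first), cd$codon_index)
    }
  }
  check_stop_edits(fixture$sequences, fixture$models, "NGG")
  sim <- simulate_genome(synthetic_spec(n_genes = 8, seed = 29))
  check_stop_edits(sim$sequences, sim$models, "NG")
})

test_that("candidate sets survive reverse-complementing the locus", {
  sim <- simulate_genome(synthetic_spec(n_genes = 6, seed = 31))
  mir <- mirror_genome(sim)
  for (pam in c("NGG", "NG")) {
    a <- design_candidates(sim$sequences, sim$models, pam = pam)
    b <- design_candidates(mir$sequences, mir$models, pam = pam)
    key <- function(x) sort(paste(x$gene_id, x$editor, x$strategy, x$subsite,
                                  x$codon_index, x$ref_codon, x$alt_codon,
                                  x$intron_index))
    expect_equal(key(a), key(b), info = pam)
  }
})
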