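test_that("FASTA reading folds case, concatenates lines, and validates", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "acgt"), fa)
  g <- read_fasta(fa)
  expect_equal(unclass(g), c(c1 = "ACGT"))
  expect_equal(nchar(g[["c1"]]), 4L)

  writeLines(c(">c1", "acgt", "ACGT", ">c2", "ttt"), fa)
  g <- read_fasta(fa)
  expect_equal(g[["c1"]], "ACGTACGT")
  expect_equal(g[["c2"]], "TTT")

  file.create(fa2 <- tempfile(fileext = ".fa"))
  expect_warning(g0 <- read_fasta(fa2), "empty")
  expect_length(g0, 0L)

  writeLines(c(">c1", "ACXT"), fa)
  expect_error(read_fasta(fa), "illegal residue 'X' in record 'c1' at position 3")

  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), fa)
  expect_error(read_fasta(fa), "duplicate")
})

test_that("GFF3 coordinates convert to 0-based half-open gene models", {
  chrom <- random_dna(400, seed = 11)
  f <- toy_gene_files(chrom, exons = rbind(c(100, 160), c(200, 260)))
  seqs <- read_fasta(f$fa)
  models <- read_gff(f$gff, seqs)
  expect_length(models, 1L)
  m <- models[[1]]
  expect_equal(m$exons, rbind(c(100L, 160L), c(200L, 260L)))
  expect_equal(m$introns, rbind(c(160L, 200L)))
  expect_equal(m$cds_length, 120L)
})

test_that("the longest-CDS mRNA is kept and short CDS flags incomplete", {
  chrom <- paste0(strrep("T", 50), "ATG", strrep("GCT", 98), "TAA",
                  strrep("T", 50))
  fa <- tempfile(fileext = ".fa"); writeLines(c(">chrT", chrom), fa)
  # two mRNAs: t1 CDS 300 nt, t2 CDS 150 nt
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t51\t350\t.\t+\t.\tID=g1",
    "chrT\ttest\tmRNA\t51\t350\t.\t+\t.\tID=t2;Parent=g1",
    "chrT\ttest\tmRNA\t51\t350\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\ttest\texon\t51\t350\t.\t+\t.\tID=t1.e;Parent=t1",
    "chrT\ttest\tCDS\t51\t350\t.\t+\t0\tID=t1.c;Parent=t1",
    "chrT\ttest\texon\t51\t200\t.\t+\t.\tID=t2.e;Parent=t2",
    "chrT\ttest\tCDS\t51\t200\t.\t+\t0\tID=t2.c;Parent=t2"), gff)
  seqs <- read_fasta(fa)
  models <- read_gff(gff, seqs)
  expect_equal(models[[1]]$mrna_id, "t1")
  expect_equal(models[[1]]$cds_length, 300L)

  # a 301-nt CDS cannot be a whole number of codons -> flagged, not errored
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t51\t351\t.\t+\t.\tID=g1",
    "chrT\ttest\tmRNA\t51\t351\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\ttest\texon\t51\t351\t.\t+\t.\tID=t1.e;Parent=t1",
    "chrT\ttest\tCDS\t51\t351\t.\t+\t0\tID=t1.c;Parent=t1"), gff)
  models <- read_gff(gff, seqs)
  expect_false(models[[1]]$complete)
  expect_match(models[[1]]$flag, "cds_not_multiple_of_3")

  # orphan CDS skipped with a warning; feature past the chromosome errors
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t51\t350\t.\t+\t.\tID=g1",
    "chrT\ttest\tmRNA\t51\t350\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\ttest\texon\t51\t350\t.\t+\t.\tID=t1.e;Parent=t1",
    "chrT\ttest\tCDS\t51\t350\t.\t+\t0\tID=t1.c;Parent=t1",
    "chrT\ttest\tCDS\t51\t350\t.\t+\t0\tID=tx.c;Parent=tX"), gff)
  expect_warning(read_gff(gff, seqs), "without a parent mRNA")
  writeLines(c(
    "##gff-version 3",
    "chrT\ttest\tgene\t51\t9999\t.\t+\t.\tID=g1",
    "chrT\ttest\tmRNA\t51\t9999\t.\t+\t.\tID=t1;Parent=g1",
    "chrT\ttest\texon\t51\t9999\t.\t+\t.\tID=t1.e;Parent=t1",
    "chrT\ttest\tCDS\t51\t9999\t.\t+\t0\tID=t1.c;Parent=t1"), gff)
  expect_error(read_gff(gff, seqs), "beyond")
})

test_that("spliced CDS respects strand and splicing, preserving frame", {
  # plus strand, single exon
  chrom <- paste0("TTTT", "ATGAAATAA", "TTTT")
  f <- toy_gene_files(chrom, exons = rbind(c(4, 13)))
  seqs <- read_fasta(f$fa)
  m <- read_gff(f$gff, seqs)[[1]]
  expect_equal(spliced_cds(m, seqs), "ATGAAATAA")

  # minus strand: plus-strand text TTACATTTTCAT reads ATGAAAATGTAA
  chrom <- paste0("GGGG", "TTACATTTTCAT", "GGGG")
  f <- toy_gene_files(chrom, exons = rbind(c(4, 16)), strand = "-")
  seqs <- read_fasta(f$fa)
  m <- read_gff(f$gff, seqs)[[1]]
  cds <- spliced_cds(m, seqs)
  expect_equal(cds, "ATGAAAATGTAA")
  expect_equal(substr(cds, 1, 3), "ATG")

  # two CDS segments split mid-codon: ATGAA | intron | ATAA
  chrom <- paste0("CC", "ATGAA", "GTTTTTTTAG", "ATAA", "CC")
  f <- toy_gene_files(chrom, exons = rbind(c(2, 7), c(17, 21)))
  seqs <- read_fasta(f$fa)
  m <- read_gff(f$gff, seqs)[[1]]
  expect_true(m$complete)
  cds <- spliced_cds(m, seqs)
  expect_equal(cds, "ATGAAATAA")
  aa <- oracle_translate(cds)
  expect_equal(aa, "MK*")   # hand translation: ATG AAA TAA
})

test_that("every complete gene translates with exactly one terminal stop", {
  sim <- simulate_genome(synthetic_spec(n_genes = 15, seed = 3))
  for (m in sim$models) {
    aa <- oracle_translate(spliced_cds(m, sim$sequences))
    stops <- gregexpr("*", aa, fixed = TRUE)[[1]]
    expect_equal(as.integer(stops), nchar(aa))
  }
})

test_that("reverse complement is correct and involutive", {
  expect_equal(revcomp("ATGC"), "GCAT")
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("NA"), "TN")
  expect_error(revcomp("ACGU"), "illegal")
  set.seed(42)
  for (i in 1:20) {
    s <- random_dna(sample(1:80, 1))
    expect_equal(revcomp(revcomp(s)), s)
    expect_equal(revcomp(s), oracle_revcomp(s))
  }
})

test_that("gene models round-trip through the GFF3 writer", {
  sim <- simulate_genome(synthetic_spec(n_genes = 8, seed = 5))
  gff <- tempfile(fileext = ".gff3")
  write_gff(sim$models, gff)
  models2 <- read_gff(gff, sim$sequences)
  expect_length(models2, length(sim$models))
  for (i in seq_along(sim$models)) {
    a <- sim$models[[i]]; b <- models2[[i]]
    expect_equal(a$gene_id, b$gene_id)
    expect_equal(a$strand, b$strand)
    expect_equal(unname(a$exons), unname(b$exons))
    expect_equal(unname(a$cds), unname(b$cds))
    expect_equal(unname(a$introns), unname(b$introns))
    expect_true(b$complete)
  }
})
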