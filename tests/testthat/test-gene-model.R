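test_that("gene model invariants are enforced", {
  g <- strrep("ACGT", 100)
  expect_error(gene_model("g", g, rbind(c(0, 100), c(50, 150)), 10),
               "overlap")
  expect_error(gene_model("g", g, rbind(c(0, 100)), 200), "cds_start")
  expect_error(gene_model("g", g, rbind(c(0, 500)), 10), "outside")
  m <- gene_model("g", g, rbind(c(0, 300)), 0)
  expect_s3_class(m, "gene_model")
  expect_identical(splice_out(m), substr(g, 1, 300))
})

test_that("splice_out concatenates exon subsets and rejects bad subsets", {
  set.seed(1)
  g <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  m <- gene_model("g", g, rbind(c(0, 200), c(300, 500), c(600, 900)), 5)
  full <- paste0(substr(g, 1, 200), substr(g, 301, 500), substr(g, 601, 900))
  expect_identical(constitutive_mrna(m), full)
  # string-surgery oracle for an exon-2 skip
  expect_identical(splice_out(m, c(1, 3)),
                   paste0(substr(g, 1, 200), substr(g, 601, 900)))
  expect_identical(splice_out(m, integer(0)), "")
  expect_error(splice_out(m, c(2, 1)), "increasing")
  expect_error(splice_out(m, 4), "range")
  # associativity with interval concatenation
  expect_identical(paste0(splice_out(m, 1:2), splice_out(m, 3)),
                   splice_out(m, 1:3))
})

test_that("translation scans for the first in-frame stop", {
  pr <- translate_and_scan("ATGTAA", 0)
  expect_identical(pr$peptide, "M")
  expect_identical(pr$first_stop_codon_index, 2L)
  expect_false(pr$premature)           # stop is the terminal codon
  # N never yields a stop, the residue is X
  pr2 <- translate_and_scan("ATGTANTAA", 0)
  expect_identical(pr2$full_translation, "MX*")
  expect_identical(pr2$first_stop_codon_index, 3L)
  # trailing partial codon ignored
  expect_identical(translate_and_scan("ATGAAAC", 0)$n_codons, 2L)
  # premature relative to an annotated CDS length
  expect_true(translate_and_scan("ATGTAAACG", 0, cds_codon_count = 3)$premature)
})

test_that("a long stop-free frame is reported as such", {
  # 999-nt ORF sampled codon-wise from the 61 sense codons; verified open
  # by an independent codon scan
  set.seed(42)
  sense <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T"),
                                     c("A", "C", "G", "T")), 1L,
                         paste0, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  s <- paste(sample(sense, 333L, replace = TRUE), collapse = "")
  codons <- substring(s, seq(1, 997, 3), seq(3, 999, 3))
  expect_false(any(codons %in% c("TAA", "TAG", "TGA")))
  pr <- translate_and_scan(s, 0)
  expect_true(is.na(pr$first_stop_codon_index))
  expect_false(pr$premature)
})

test_that("exon-local codon numbering restarts at each exon", {
  sim <- small_sim()
  m <- sim$models[[4L]]                # pseudogene: stop at CDS codon 94
  expect_identical(m$cds_codon_count, 94L)
  loc <- codon_exon_position(m, 94L)
  expect_identical(loc$exon, 2L)
  expect_identical(loc$local_triplet, 65L)
  # first codon fully in exon 2 is CDS codon 30 (exon 1 holds 29 codons)
  expect_identical(codon_exon_position(m, 30L)$local_triplet, 1L)
  expect_identical(codon_exon_position(m, 29L)$exon, 1L)
})

test_that("minus-strand gene models are normalized to gene strand", {
  set.seed(7)
  plus <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  # gene annotated on the minus strand of `plus`: exons 50-150 and 250-350
  # (1-based inclusive), CDS starting at the minus-strand-most CDS end 340
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeLines(c("##gff-version 3",
               "chr1\t.\tgene\t50\t350\t.\t-\t.\tID=gneg",
               "chr1\t.\texon\t50\t150\t.\t-\t.\tID=gneg.e1;Parent=gneg",
               "chr1\t.\texon\t250\t350\t.\t-\t.\tID=gneg.e2;Parent=gneg",
               "chr1\t.\tCDS\t60\t340\t.\t-\t0\tID=gneg.cds;Parent=gneg"),
             gff)
  writeLines(c(">chr1", plus), fa)
  m <- read_gene_model(gff, fa)
  # hand-computed reverse complement
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rc <- paste(rev(comp[strsplit(plus, "")[[1]]]), collapse = "")
  expect_identical(m$genomic_seq, rc)
  L <- nchar(plus)
  expect_identical(unname(m$exons[1, ]), c(L - 350L, L - 249L))
  expect_identical(unname(m$exons[2, ]), c(L - 150L, L - 49L))
  expect_identical(m$cds_start, L - 340L)
})

test_that("gene models round-trip through GFF3 + FASTA unchanged", {
  sim <- small_sim()
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  suppressWarnings(write_gene_model(sim$models, gff, fa))
  back <- read_gene_model(gff, fa)
  for (id in names(sim$models)) {
    m0 <- sim$models[[id]]; m1 <- back[[id]]
    expect_identical(m1$genomic_seq, m0$genomic_seq)
    expect_identical(unname(m1$exons), unname(m0$exons))
    expect_identical(m1$cds_start, m0$cds_start)
    expect_identical(m1$domain_labels, m0$domain_labels)
    expect_identical(m1$cds_codon_count, m0$cds_codon_count)
  }
  # constitutive translation of every functional synthetic allele is intact
  for (g in c(1L, 3L)) {
    m <- sim$models[[g]]
    for (a in sim$truth$alleles[[g]]) {
      pr <- translate_and_scan(a, cds_offset_in_mrna(m), m$cds_codon_count)
      expect_false(pr$premature)
    }
  }
})
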