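make_clones <- function(seqs, animals, batches,
                        gene = "gX", ids = NULL) {
  data.frame(clone_id = ids %||% sprintf("c%02d", seq_along(seqs)),
             animal = animals, gene = gene, pcr_batch = batches,
             seq = seqs, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# pre-classified "all constitutive" shim so clustering tests need no models
all_ok <- function(clones) {
  data.frame(clone_id = clones$clone_id, gene = clones$gene, status = "ok",
             event_key = "", n_events = 0L, stringsAsFactors = FALSE)
}

test_that("clusters group identical sequences exactly", {
  cl <- make_clones(c("AAAA", "AAAA", "AAAA"), rep("a1", 3), rep("PCR1", 3))
  clus <- cluster_clones(cl, NULL, classified = all_ok(cl))
  expect_length(clus, 1L)
  expect_identical(nrow(clus[[1L]]$support), 3L)
  # one substitution separates clusters
  cl2 <- make_clones(c("AAAA", "AAAT"), c("a1", "a1"), c("PCR1", "PCR1"))
  expect_length(cluster_clones(cl2, NULL, classified = all_ok(cl2)), 2L)
})

test_that("the evidence rule validates exactly the independent pairs", {
  # different monkeys, same batch: validated
  c1 <- make_clones(c("AAAA", "AAAA"), c("a1", "a2"), c("PCR1", "PCR1"))
  # one monkey, independent PCRs: validated
  c2 <- make_clones(c("CCCC", "CCCC"), c("a1", "a1"), c("PCR1", "PCR2"))
  # one monkey, one batch: singleton regardless of count
  c3 <- make_clones(c("GGGG", "GGGG"), c("a1", "a1"), c("PCR1", "PCR1"))
  cl <- rbind(c1, c2, c3)
  calls <- call_alleles(cluster_clones(cl, NULL, classified = all_ok(cl)))
  status <- vapply(calls, function(x)
    stats::setNames(x$status, x$seq), character(1))
  expect_identical(unname(status[vapply(calls, `[[`, "", "seq") == "AAAA"]), "validated")
  expect_identical(unname(status[vapply(calls, `[[`, "", "seq") == "CCCC"]), "validated")
  expect_identical(unname(status[vapply(calls, `[[`, "", "seq") == "GGGG"]), "singleton")
  # singletons carry no allele name and never reach genotypes
  geno <- genotype_animals(calls)
  named <- stats::na.omit(c(geno$allele1, geno$allele2))
  expect_false(any(is.na(named)))
  expect_identical(sort(unique(geno$gene)), "gX")
  expect_false("GGGG" %in% vapply(
    Filter(function(x) x$status == "validated", calls), `[[`, "", "seq"))
})

test_that("allele naming is serial per gene and stable", {
  cl <- make_clones(c("AAAA", "AAAA", "TTTT", "TTTT"),
                    c("a1", "a2", "a1", "a2"), rep("PCR1", 4))
  calls <- call_alleles(cluster_clones(cl, NULL, classified = all_ok(cl)))
  names1 <- sort(vapply(calls, `[[`, character(1), "allele_name"))
  expect_identical(names1, c("gX*01", "gX*02"))
  calls2 <- call_alleles(cluster_clones(cl, NULL, classified = all_ok(cl)))
  expect_identical(vapply(calls2, `[[`, "", "allele_name"),
                   vapply(calls, `[[`, "", "allele_name"))
})

test_that("more than two validated alleles in one animal is an error", {
  cl <- make_clones(rep(c("AAAA", "CCCC", "GGGG"), each = 2),
                    rep("a1", 6), rep(c("PCR1", "PCR2"), 3))
  calls <- call_alleles(cluster_clones(cl, NULL, classified = all_ok(cl)))
  expect_error(genotype_animals(calls), "contamination|collapsed")
})

test_that("gene assignment by 31-mer vote matches the simulation truth", {
  sim <- small_sim(seed = 41L)
  cfg <- sim$config
  cfg$clone_depth <- 4L
  clones <- simulate_clone_library(sim, cfg)
  assigned <- assign_genes(clones, sim$models)
  expect_identical(assigned, clones$gene)
  # a sequence matching nothing stays unassigned, with a warning
  junk <- clones[1L, ]; junk$seq <- strrep("ACGT", 100L)
  expect_warning(a2 <- assign_genes(junk, sim$models), "unassigned")
  expect_true(is.na(a2))
})

test_that("error-free synthetic data recovers the true allele set exactly", {
  sim <- small_sim(seed = 51L)
  clones <- simulate_clone_library(sim)
  classified <- classify_transcripts(clones, sim$models)
  calls <- call_alleles(cluster_clones(clones, sim$models, classified))
  expect_setequal(validated_seqs(calls), truth_allele_seqs(sim))
  # genotypes match truth per animal and gene (compared by allele sequence)
  geno <- genotype_animals(calls)
  name2seq <- local({
    v <- Filter(function(x) x$status == "validated", calls)
    stats::setNames(vapply(v, `[[`, "", "seq"), vapply(v, `[[`, "", "allele_name"))
  })
  gt <- true_genotypes(sim)
  expect_identical(nrow(geno), nrow(gt))
  for (i in seq_len(nrow(gt))) {
    row <- geno[geno$animal == gt$animal[i] & geno$gene == gt$gene[i], ]
    got <- sort(unname(name2seq[stats::na.omit(c(row$allele1, row$allele2))]))
    tru <- sort(unname(sim$truth$alleles[[gt$gene[i]]][
      stats::na.omit(c(gt$allele1[i], gt$allele2[i]))]))
    expect_identical(got, tru)
  }
})

test_that("with sequencing errors, clusters exceed true alleles but all truth is found", {
  cfg <- cohort_config(seed = 52L, generations = 2L, n_families = 1L)
  sim <- simulate_family(cfg)
  clones <- simulate_clone_library(sim)
  classified <- classify_transcripts(clones, sim$models)
  clusters <- cluster_clones(clones, sim$models, classified)
  truth <- truth_allele_seqs(sim)
  expect_gte(length(clusters), length(truth))     # error singletons
  calls <- call_alleles(clusters)
  expect_true(all(truth %in% validated_seqs(calls)))
  # no singleton is ever genotyped: every genotyped name is a validated call
  geno <- tryCatch(genotype_animals(calls), error = function(e) NULL)
  if (!is.null(geno)) {
    validated_names <- vapply(Filter(function(x) x$status == "validated", calls),
                              `[[`, character(1), "allele_name")
    named <- stats::na.omit(c(geno$allele1, geno$allele2))
    expect_true(all(named %in% validated_names))
  }
})
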