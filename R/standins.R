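#' Synthetic stand-ins for the deposited allele sequences
#'
#' The worked examples of this analysis chain refer to allele sequences
#' deposited in public archives. This package ships no external data;
#' instead, this generator builds fully synthetic stand-in sequences that
#' embody the documented properties of those deposits, so the translation,
#' stop-scanning and allotype machinery can be exercised end to end:
#'
#' * seven pseudogene exon-1+2 transcripts sharing a premature stop at
#'   exon-2 local triplet 65 (CDS codon 94), differing elsewhere;
#' * a chimeric baboon-like pseudogene transcript with a 258-nt insertion
#'   after exon 1 that brings a stop at CDS codon 32;
#' * eight alleles of a BTN3A1-like gene encoding exactly seven distinct
#'   proteins (one pair differs only synonymously);
#' * twelve alleles of a BTN3A3-like gene encoding exactly six proteins
#'   (six substitution variants, each with a synonymous twin).
#'
#' Everything is deterministic for a fixed seed. These sequences are
#' synthetic constructions, not the deposited data: results computed from
#' them validate the package's computations, not the archived sequences.
#'
#' @param seed integer seed.
#' @return list with `models` (the underlying [gene_model()]s),
#'   `btn3a1_alleles` (8 mRNAs), `btn3a3_alleles` (12 mRNAs),
#'   `pseudo_exon2_alleles` (7 exon-1+2 transcripts), `pseudo_model`,
#'   `baboon` (`seq`, `cds_offset`), and the shared `cds_offset`.
#' @export
standin_deposited_alleles <- function(seed = 2024L) {
  cfg <- cohort_config(seed = seed, alleles_per_gene = 1L,
                       n_founder_haplotypes = 1L, generations = 1L,
                       n_families = 1L)
  sim <- simulate_family(cfg)
  models <- sim$models
  off <- cfg$utr5

  nonsyn <- function(seq, codon_i) .substitute_codon(seq, off, codon_i, syn = FALSE)
  syn <- function(seq, from_codon) .substitute_codon(seq, off, from_codon, syn = TRUE)

  ref1 <- constitutive_mrna(models[[1L]])
  a1 <- vapply(1:7, function(i) nonsyn(ref1, 100L + 10L * i), character(1))
  a1 <- c(a1, syn(a1[1L], 200L))
  names(a1) <- sprintf("%s*%02d", models[[1L]]$gene_id, 1:8)

  ref3 <- constitutive_mrna(models[[3L]])
  base3 <- vapply(1:6, function(i) nonsyn(ref3, 100L + 10L * i), character(1))
  a3 <- c(base3, vapply(base3, syn, character(1), from_codon = 250L))
  names(a3) <- sprintf("%s*%02d", models[[3L]]$gene_id, 1:12)

  m4 <- models[[4L]]
  ref4 <- splice_out(m4, 1:2)
  p7 <- c(ref4, vapply(1:6, function(i) nonsyn(ref4, 40L + 5L * i), character(1)))
  names(p7) <- sprintf("%s*%02d", m4$gene_id, 1:7)

  # chimeric baboon-like pseudogene: 258-nt insert after exon 1, carrying a
  # stop at CDS codon 32 (exon 1 contributes 29 complete codons)
  set.seed(seed + 1L)
  insert <- sample(BASES, 258L, replace = TRUE)
  insert[1:6] <- c("C", "A", "A", "C", "A", "A")   # codons 30-31: Gln Gln
  insert[7:9] <- c("T", "A", "A")                  # codon 32: stop
  exon1 <- substr(ref3, 1L, 150L)
  baboon <- paste0(exon1, paste(insert, collapse = ""),
                   substr(ref3, 151L, nchar(ref3)))

  list(models = models,
       btn3a1_alleles = a1, btn3a3_alleles = a3,
       pseudo_exon2_alleles = p7, pseudo_model = m4,
       baboon = list(seq = baboon, cds_offset = off, insert_length = 258L),
       cds_offset = off)
}

# One deterministic substitution at codon `codon_i` (1-based from the CDS
# start at `off`): synonymous (third-position T<->C, scanning forward from
# codon_i for an eligible codon) or nonsynonymous (second-position change
# avoiding stop codons).
.substitute_codon <- function(seq, off, codon_i, syn = FALSE) {
  sv <- strsplit(seq, "")[[1L]]
  pos0 <- function(i) off + 3L * (i - 1L)          # 0-based first base
  if (syn) {
    n_codons <- (length(sv) - off) %/% 3L
    for (i in codon_i:n_codons) {
      third <- pos0(i) + 3L                        # 1-based index of 3rd base
      if (sv[third] %in% c("T", "C")) {
        sv[third] <- if (sv[third] == "T") "C" else "T"
        return(paste(sv, collapse = ""))
      }
    }
    stop("no synonymous third-position site found")
  }
  second <- pos0(codon_i) + 2L
  codon <- sv[(second - 1L):(second + 1L)]
  for (b in setdiff(BASES, codon[2L])) {
    cand <- c(codon[1L], b, codon[3L])
    if (!paste(cand, collapse = "") %in% c("TAA", "TAG", "TGA")) {
      sv[second] <- b
      return(paste(sv, collapse = ""))
    }
  }
  stop("could not place a nonsynonymous substitution")
}
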