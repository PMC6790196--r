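#' Configuration of the synthetic cohort generator
#'
#' The defaults emulate the study conditions of a clone-based survey of a
#' linked four-gene butyrophilin-like cluster: two pedigreed families of
#' four generations (13 animals each), four linked genes (one pseudogene),
#' clone depth 32 per animal and gene, Sanger-clone substitution errors, and
#' an alternative-splicing spectrum in which transmembrane-exon (exon 4)
#' skipping occurs in two of the three functional genes while an
#' exon-2-internal 112-nt deletion bounded by an alternative 3' and 5'
#' splice site occurs in all genes.
#'
#' Exon lengths follow the family's architecture: a short first exon with a
#' 5' UTR and 87 coding nt, a long IgV exon 2 (351 nt), an IgC exon 3, a
#' transmembrane exon 4 whose length is a multiple of 3, four very short
#' heptad exons, and a large terminal B30.2 exon. All exon lengths are
#' multiples of 3 and boundaries are codon-aligned, so single-exon skips are
#' frame-preserving, as observed for this family.
#'
#' @param n_genes number of linked genes (default 4; the last is a pseudogene).
#' @param pseudogene index of the pseudogene (engineered in-frame stop at
#'   exon-2 local triplet 65, i.e. CDS codon 94); `NA` for none.
#' @param exon7_stop_gene index of the gene whose natural stop lies in its
#'   exon 7 (the BTN3A2 analogue, which lacks the B30.2 domain); `NA` for none.
#' @param exon_lengths,intron_lengths per-exon/per-intron lengths in nt,
#'   shared by all genes.
#' @param utr5 offset of the start codon within exon 1.
#' @param exon9_coding coding nt within the terminal exon (incl. stop codon).
#' @param exon2_del `c(offset, len)`: the exon-2-internal deletion event,
#'   0-based offset within exon 2 and deleted length (112 nt, not a multiple
#'   of 3, hence frameshifting).
#' @param n_founder_haplotypes size of the founder haplotype pool.
#' @param alleles_per_gene alleles in the population per gene (recycled).
#' @param snp_rate substitutions per exonic site between an allele and the
#'   gene reference.
#' @param snp_min_junction_dist minimum distance (nt) of allelic SNPs from
#'   any splice junction or planted feature.
#' @param generations pedigree depth per family (1 = founders only).
#' @param n_families number of independent families drawing from the same
#'   haplotype pool.
#' @param clone_depth cDNA clones per animal and gene.
#' @param clone_error_rate substitution rate per site per clone.
#' @param recombination_rate per-meiosis probability of a crossover in each
#'   inter-gene interval (0 = complete linkage).
#' @param as_spectrum list of planted event definitions, each a list with
#'   `mechanism` (`"exon_skip"` or `"alt_pair_deletion"`), `exons` or `exon`,
#'   `genes` (indices), `freq` (per-clone probability).
#' @param seed integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 4L,
                          pseudogene = 4L,
                          exon7_stop_gene = 2L,
                          exon_lengths = c(150L, 351L, 330L, 117L, 24L, 27L, 36L, 21L, 807L),
                          intron_lengths = c(180L, 150L, 140L, 120L, 110L, 100L, 130L, 160L),
                          utr5 = 63L,
                          exon9_coding = 690L,
                          exon2_del = c(offset = 100L, len = 112L),
                          n_founder_haplotypes = 8L,
                          alleles_per_gene = 4L,
                          snp_rate = 0.002,
                          snp_min_junction_dist = 10L,
                          generations = 4L,
                          n_families = 2L,
                          clone_depth = 32L,
                          clone_error_rate = 5e-4,
                          recombination_rate = 0,
                          as_spectrum = NULL,
                          seed = 1L) {
  if (is.null(as_spectrum)) {
    functional <- setdiff(seq_len(n_genes), pseudogene)
    as_spectrum <- list(
      list(mechanism = "exon_skip", exons = 4L,
           genes = functional[seq_len(min(2L, length(functional)))],
           freq = 0.06),
      list(mechanism = "alt_pair_deletion", exon = 2L,
           genes = seq_len(n_genes), freq = 0.05)
    )
  }
  cfg <- list(n_genes = as.integer(n_genes), pseudogene = pseudogene,
              exon7_stop_gene = exon7_stop_gene,
              exon_lengths = as.integer(exon_lengths),
              intron_lengths = as.integer(intron_lengths),
              utr5 = as.integer(utr5), exon9_coding = as.integer(exon9_coding),
              exon2_del = exon2_del,
              n_founder_haplotypes = as.integer(n_founder_haplotypes),
              alleles_per_gene = rep_len(as.integer(alleles_per_gene), n_genes),
              snp_rate = snp_rate,
              snp_min_junction_dist = as.integer(snp_min_junction_dist),
              generations = as.integer(generations),
              n_families = as.integer(n_families),
              clone_depth = as.integer(clone_depth),
              clone_error_rate = clone_error_rate,
              recombination_rate = recombination_rate,
              as_spectrum = as_spectrum, seed = as.integer(seed))
  freqs <- vapply(cfg$as_spectrum, `[[`, numeric(1), "freq")
  if (any(freqs < 0 | freqs > 1) || sum(freqs) > 1) {
    stop("config error: event frequencies must lie in [0,1] and sum to <= 1")
  }
  if (cfg$clone_depth < 1L) stop("config error: clone_depth must be >= 1")
  if (length(cfg$exon_lengths) < 2L) stop("config error: need >= 2 exons")
  if (length(cfg$intron_lengths) != length(cfg$exon_lengths) - 1L) {
    stop("config error: need one intron length per exon pair")
  }
  class(cfg) <- "cohort_config"
  cfg
}

BASES <- c("A", "C", "G", "T")

# Splice-site consensus planted at every synthetic junction. The donor
# window is exon[-3..-1] + intron[1..6], the acceptor the last 16 intronic
# bases (pyrimidine tract + NCAG) with a G as first exonic base.
.DONOR_EXONIC <- c("C", "A", "G")
.DONOR_INTRONIC <- c("G", "T", "A", "A", "G", "T")
.ACCEPTOR_TAIL <- c("T", "C", "T", "T", "T", "T", "C", "T", "T", "T",
                    "C", "C", "T", "C", "A", "G")

# Builds one synthetic gene: char vector genome, exon matrix, cds_start,
# plus bookkeeping of positions allelic SNPs must avoid.
.make_gene <- function(cfg, g, gene_id) {
  el <- cfg$exon_lengths; il <- cfg$intron_lengths
  nE <- length(el)
  flank <- 50L
  estart <- integer(nE); eend <- integer(nE)
  pos <- flank
  for (e in seq_len(nE)) {
    estart[e] <- pos; eend[e] <- pos + el[e]
    pos <- eend[e] + if (e < nE) il[e] else flank
  }
  L <- pos
  gv <- sample(BASES, L, replace = TRUE)
  # splice-site consensus at each junction
  for (e in seq_len(nE - 1L)) {
    gv[(eend[e] - 2L):eend[e]] <- .DONOR_EXONIC          # 1-based: eend is last exon base
    gv[(eend[e] + 1L):(eend[e] + 6L)] <- .DONOR_INTRONIC
    acc_end <- estart[e + 1L]                             # last intron base (1-based)
    gv[(acc_end - 15L):acc_end] <- .ACCEPTOR_TAIL
    gv[acc_end + 1L] <- "G"
  }
  # transcript position (1-based) -> genomic position (1-based)
  tmap <- unlist(lapply(seq_len(nE), function(e) (estart[e] + 1L):eend[e]))
  cds_start <- estart[1L] + cfg$utr5                      # 0-based genomic
  cds_t0 <- cfg$utr5                                      # 0-based transcript
  coding_len <- sum(el) - cfg$utr5 - (el[nE] - cfg$exon9_coding)
  coding_len <- coding_len - coding_len %% 3L
  n_codons <- coding_len %/% 3L
  codon_gpos <- function(i) tmap[cds_t0 + 3L * (i - 1L) + (1:3)]  # genomic 1-based
  set_codon <- function(i, codon) gv[codon_gpos(i)] <<- strsplit(codon, "")[[1]]
  get_codon <- function(i) paste(gv[codon_gpos(i)], collapse = "")
  protected <- integer(0)
  plant <- function(i, codon) {
    set_codon(i, codon)
    protected <<- c(protected, codon_gpos(i))
  }
  plant(n_codons, "TAA")                                  # terminal stop
  if (!is.na(cfg$exon7_stop_gene) && g == cfg$exon7_stop_gene && nE >= 7L) {
    first_e7 <- (sum(el[1:6]) - cfg$utr5) %/% 3L + 1L     # exon boundaries codon-aligned
    plant(first_e7 + 4L, "TAA")                           # local triplet 5 of exon 7
  }
  if (!is.na(cfg$pseudogene) && g == cfg$pseudogene) {
    first_e2 <- (el[1L] - cfg$utr5) %/% 3L + 1L
    plant(first_e2 + 64L, "TAA")                          # local triplet 65 of exon 2
  }
  # shifted-frame stop inside exon 2, revealed by the 112-nt deletion event:
  # pick an exon-2 offset p > deletion end with (p - del_len %% 3) codon-aligned
  # in the shifted frame; TAA there cannot form a main-frame stop because
  # main-frame codons read ?TA | A?? at that placement.
  del <- cfg$exon2_del
  if (nE >= 2L) {
    # a shifted-frame codon starts at exon-2 offset p (0-based) iff
    # (exon1_coding + p - del_len) %% 3 == 0; with codon-aligned exon
    # boundaries that is p == del_len (mod 3), which also guarantees the TAA
    # spans main-frame codons ?TA | A?? (never stops), so the scrub below
    # cannot disturb it.
    target <- (del[["len"]] - (el[1L] - cfg$utr5)) %% 3L
    p <- el[2L] - 6L
    p <- p - ((p - target) %% 3L)                         # near the exon-2 end
    if (p < del[["offset"]] + del[["len"]] + 3L) {
      stop("config error: exon 2 too short for the planted deletion event")
    }
    gpos <- estart[2L] + p + (1:3)                        # 1-based genomic
    gv[gpos] <- c("T", "A", "A")
    protected <- c(protected, gpos)
  }
  # scrub accidental main-frame stops (planted codons excluded)
  for (i in seq_len(n_codons)) {
    if (get_codon(i) %in% c("TAA", "TAG", "TGA") &&
        !all(codon_gpos(i) %in% protected)) {
      gv[codon_gpos(i)[1L]] <- "C"                        # CAA/CAG/CGA: never stops
    }
  }
  list(gv = gv, exons = cbind(estart, eend), cds_start = cds_start,
       tmap = tmap, n_codons = n_codons, protected = protected,
       gene_id = gene_id)
}

.domain_labels <- function(nE) {
  lab <- rep("other", nE)
  if (nE >= 2L) lab[2L] <- "IgV"
  if (nE >= 3L) lab[3L] <- "IgC"
  if (nE >= 4L) lab[4L] <- "TM"
  if (nE >= 8L) lab[5:8] <- "heptad"
  if (nE >= 9L) lab[9L] <- "B30.2"
  lab
}

# Derives allele genomic sequences from a reference gene by planting exonic
# SNPs away from junctions and engineered positions, never creating a
# main-frame stop. Allele 1 is the reference itself.
.make_alleles <- function(raw, model, n_alleles, cfg) {
  gv0 <- raw$gv
  exonic <- raw$tmap                                      # 1-based genomic, exonic
  d <- cfg$snp_min_junction_dist
  near_junction <- unlist(lapply(seq_len(nrow(raw$exons)), function(e) {
    c((raw$exons[e, 1L] + 1L):min(raw$exons[e, 1L] + d, raw$exons[e, 2L]),
      max(raw$exons[e, 2L] - d + 1L, raw$exons[e, 1L] + 1L):raw$exons[e, 2L])
  }))
  del <- cfg$exon2_del
  del_guard <- if (nrow(raw$exons) >= 2L) {
    b1 <- raw$exons[2L, 1L] + del[["offset"]]             # 0-based boundaries
    b2 <- b1 + del[["len"]]
    c((b1 - d + 1L):(b1 + d), (b2 - d + 1L):(b2 + d))
  } else integer(0)
  eligible <- setdiff(exonic, c(near_junction, raw$protected, del_guard))
  alleles <- vector("list", n_alleles)
  alleles[[1L]] <- gv0
  seen <- paste(gv0[exonic], collapse = "")
  for (a in seq_len(n_alleles)[-1L]) {
    for (attempt in 1:200) {
      n_snp <- max(1L, stats::rpois(1L, cfg$snp_rate * length(eligible)))
      pos <- sample(eligible, min(n_snp, length(eligible)))
      gv <- gv0
      gv[pos] <- vapply(gv0[pos],
                        function(b) sample(setdiff(BASES, b), 1L), character(1))
      key <- paste(gv[exonic], collapse = "")
      if (key %in% seen) next
      mrna <- paste(gv[raw$tmap], collapse = "")
      pr <- translate_and_scan(mrna, cfg$utr5, model$cds_codon_count)
      if (!is.na(pr$first_stop_codon_index) &&
          pr$first_stop_codon_index < model$cds_codon_count) next
      alleles[[a]] <- gv
      seen <- c(seen, key)
      break
    }
    if (is.null(alleles[[a]])) {
      stop("config error: could not place distinct alleles (mutational space exhausted)")
    }
  }
  alleles
}

.build_pedigree <- function(cfg) {
  one_family <- function(f) {
    id <- function(x) sprintf("F%d-%s", f, x)
    rows <- list(
      data.frame(animal = id(c("M1", "F1")), sire = NA_character_,
                 dam = NA_character_, sex = c("m", "f"), family = f,
                 generation = 1L, stringsAsFactors = FALSE)
    )
    parents <- c(id("M1"), id("F1"))
    kids <- c("C", "D", "E")
    for (g in seq_len(cfg$generations - 1L)) {
      tag <- kids[g]
      ch <- sprintf("%s%d", tag, 1:3)
      rows[[length(rows) + 1L]] <- data.frame(
        animal = id(ch), sire = parents[1L], dam = parents[2L],
        sex = c("m", "f", "f"), family = f, generation = g + 1L,
        stringsAsFactors = FALSE)
      if (g < cfg$generations - 1L) {
        sp <- sprintf("S%d", g + 1L)                      # founder spouse
        rows[[length(rows) + 1L]] <- data.frame(
          animal = id(sp), sire = NA_character_, dam = NA_character_,
          sex = "f", family = f, generation = g + 1L, stringsAsFactors = FALSE)
        parents <- c(id(ch[1L]), id(sp))
      }
    }
    do.call(rbind, rows)
  }
  ped <- do.call(rbind, lapply(seq_len(cfg$n_families), one_family))
  rownames(ped) <- NULL
  ped
}

#' Simulate a gene family, pedigree and ground truth
#'
#' Builds the synthetic gene models (reference alleles), a founder haplotype
#' pool, one or more multi-generation families, and the Mendelian
#' transmission of whole haplotypes down each pedigree (whole tuples
#' transmit intact when `recombination_rate` is 0, emulating tight linkage).
#' Fully deterministic for a fixed configuration.
#'
#' @param config a [cohort_config()].
#' @return list of class `family_sim` with `models` (list of [gene_model()]),
#'   `pedigree` (data frame: animal, sire, dam, sex, family, generation),
#'   `truth` (allele sequences per gene, founder haplotype pool, per-animal
#'   transmitted haplotypes and founder-chromosome labels, recombination
#'   events), and the `config`.
#' @export
simulate_family <- function(config = cohort_config()) {
  cfg <- config
  set.seed(cfg$seed)
  gene_ids <- sprintf("synBTN3A%d", seq_len(cfg$n_genes))
  if (!is.na(cfg$pseudogene)) {
    gene_ids[cfg$pseudogene] <- sprintf("synBTN3A%dL", cfg$pseudogene - 1L)
  }
  nE <- length(cfg$exon_lengths)
  raws <- lapply(seq_len(cfg$n_genes), function(g) .make_gene(cfg, g, gene_ids[g]))
  models <- lapply(raws, function(r) {
    gene_model(r$gene_id, paste(r$gv, collapse = ""), r$exons, r$cds_start,
               domain_labels = .domain_labels(nE))
  })
  names(models) <- gene_ids
  allele_gv <- lapply(seq_len(cfg$n_genes), function(g) {
    .make_alleles(raws[[g]], models[[g]], cfg$alleles_per_gene[g], cfg)
  })
  allele_names <- lapply(seq_len(cfg$n_genes), function(g) {
    sprintf("%s*%02d", gene_ids[g], seq_len(cfg$alleles_per_gene[g]))
  })
  allele_mrna <- lapply(seq_len(cfg$n_genes), function(g) {
    v <- vapply(allele_gv[[g]], function(gv) paste(gv[raws[[g]]$tmap], collapse = ""),
                character(1))
    names(v) <- allele_names[[g]]
    v
  })
  allele_genomic <- lapply(seq_len(cfg$n_genes), function(g) {
    v <- vapply(allele_gv[[g]], function(gv) paste(gv, collapse = ""), character(1))
    names(v) <- allele_names[[g]]
    v
  })
  names(allele_mrna) <- names(allele_genomic) <- gene_ids

  # founder haplotype pool: distinct tuples of allele indices
  H <- cfg$n_founder_haplotypes
  pool <- matrix(0L, H, cfg$n_genes, dimnames = list(NULL, gene_ids))
  seen <- character(0)
  h <- 1L
  guard <- 0L
  while (h <= H) {
    tup <- vapply(cfg$alleles_per_gene, function(k) sample.int(k, 1L), integer(1))
    key <- paste(tup, collapse = ",")
    if (!key %in% seen) {
      pool[h, ] <- tup; seen <- c(seen, key); h <- h + 1L
    }
    guard <- guard + 1L
    if (guard > 10000L) stop("config error: fewer distinct haplotypes than requested")
  }

  ped <- .build_pedigree(cfg)
  n <- nrow(ped)
  hap_sire <- vector("list", n); hap_dam <- vector("list", n)
  chrom_sire <- character(n); chrom_dam <- character(n)
  names(hap_sire) <- names(hap_dam) <- ped$animal
  chrom_counter <- 0L
  rec_events <- list()
  gamete <- function(i) {
    # meiosis of animal at row i: returns list(tuple, chrom, rec)
    h <- list(hap_sire[[i]], hap_dam[[i]])
    ch <- c(chrom_sire[i], chrom_dam[i])
    pick <- sample.int(2L, 1L)
    tup <- h[[pick]]; lab <- ch[pick]; rec <- integer(0)
    if (cfg$recombination_rate > 0 && cfg$n_genes > 1L) {
      cur <- pick
      for (iv in seq_len(cfg$n_genes - 1L)) {
        if (stats::runif(1L) < cfg$recombination_rate) {
          cur <- 3L - cur
          rec <- c(rec, iv)
        }
        tup[iv + 1L] <- h[[cur]][iv + 1L]
      }
      if (length(rec)) lab <- paste0(lab, "r")
    }
    list(tuple = tup, chrom = lab, rec = rec)
  }
  for (i in seq_len(n)) {
    if (is.na(ped$sire[i])) {                              # founder
      hs <- pool[sample.int(H, 1L), ]
      hd <- pool[sample.int(H, 1L), ]
      hap_sire[[i]] <- hs; hap_dam[[i]] <- hd
      chrom_sire[i] <- sprintf("chr%02d", chrom_counter + 1L)
      chrom_dam[i] <- sprintf("chr%02d", chrom_counter + 2L)
      chrom_counter <- chrom_counter + 2L
    } else {
      is_ <- match(ped$sire[i], ped$animal)
      id_ <- match(ped$dam[i], ped$animal)
      gs <- gamete(is_); gd <- gamete(id_)
      hap_sire[[i]] <- gs$tuple; hap_dam[[i]] <- gd$tuple
      chrom_sire[i] <- gs$chrom; chrom_dam[i] <- gd$chrom
      for (iv in gs$rec) {
        rec_events[[length(rec_events) + 1L]] <-
          data.frame(child = ped$animal[i], parent = ped$sire[i], interval = iv)
      }
      for (iv in gd$rec) {
        rec_events[[length(rec_events) + 1L]] <-
          data.frame(child = ped$animal[i], parent = ped$dam[i], interval = iv)
      }
    }
  }
  truth <- list(
    gene_ids = gene_ids,
    alleles = allele_mrna,
    allele_genomic = allele_genomic,
    founder_haplotypes = pool,
    hap_sire = hap_sire, hap_dam = hap_dam,
    chrom_sire = stats::setNames(chrom_sire, ped$animal),
    chrom_dam = stats::setNames(chrom_dam, ped$animal),
    recombinations = if (length(rec_events)) do.call(rbind, rec_events) else
      data.frame(child = character(0), parent = character(0), interval = integer(0))
  )
  structure(list(models = models, pedigree = ped, truth = truth, config = cfg),
            class = "family_sim")
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("<family_sim> %d genes, %d animals in %d families, seed %d\n",
              length(x$models), nrow(x$pedigree), x$config$n_families,
              x$config$seed))
  invisible(x)
}

#' Per-animal true genotypes of a simulated cohort
#'
#' Convenience accessor over the ground truth: for each animal and gene, the
#' (at most two) allele names carried.
#'
#' @param sim a [simulate_family()] result.
#' @return data frame with columns `animal`, `gene`, `allele1`, `allele2`
#'   (`allele2` is `NA` for homozygotes).
#' @export
true_genotypes <- function(sim) {
  ped <- sim$pedigree
  genes <- sim$truth$gene_ids
  out <- list()
  for (i in seq_len(nrow(ped))) {
    a <- ped$animal[i]
    for (g in seq_along(genes)) {
      a1 <- names(sim$truth$alleles[[g]])[sim$truth$hap_sire[[a]][g]]
      a2 <- names(sim$truth$alleles[[g]])[sim$truth$hap_dam[[a]][g]]
      pair <- sort(unique(c(a1, a2)))
      out[[length(out) + 1L]] <- data.frame(
        animal = a, gene = genes[g], allele1 = pair[1L],
        allele2 = if (length(pair) > 1L) pair[2L] else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Builds the transcript of one allele under one planted event.
.event_transcript <- function(model, allele_genomic, spec_entry, cfg) {
  m <- model
  m$genomic_seq <- allele_genomic
  if (is.null(spec_entry)) {
    return(list(seq = constitutive_mrna(m), key = "", mechanism = ""))
  }
  if (spec_entry$mechanism == "exon_skip") {
    keep <- setdiff(seq_len(nrow(m$exons)), spec_entry$exons)
    lens <- exon_lengths(m)
    delta <- -sum(lens[spec_entry$exons])
    mech <- if (length(spec_entry$exons) > 1L) "multi_exon_skip" else "exon_skip"
    key <- sprintf("%s[%s]%+d", mech,
                   paste(spec_entry$exons, collapse = "+"), delta)
    list(seq = splice_out(m, keep), key = key, mechanism = mech)
  } else if (spec_entry$mechanism == "alt_pair_deletion") {
    e <- spec_entry$exon
    del <- cfg$exon2_del
    t0 <- genomic_to_transcript(m, m$exons[e, "start"] + del[["offset"]])
    full <- constitutive_mrna(m)
    seq <- paste0(substr(full, 1L, t0), substr(full, t0 + del[["len"]] + 1L, nchar(full)))
    key <- sprintf("alt3ss+alt5ss[%d]%+d", e, -del[["len"]])
    list(seq = seq, key = key, mechanism = "alt3ss+alt5ss")
  } else {
    stop(sprintf("config error: unknown planted mechanism '%s'", spec_entry$mechanism))
  }
}

#' Simulate a cDNA clone library for a cohort
#'
#' For every animal and gene, draws `clone_depth` clones. Each clone picks
#' one of the animal's two alleles at random, is constitutive or carries one
#' planted alternative-splicing event per the configured spectrum, and then
#' receives substitution errors at `clone_error_rate` (substitutions only:
#' every length change in a clone is a splice event, emulating the
#' negligible indel rate of Sanger clone consensus). Each animal's library
#' for a gene is split into two PCR batches so the two-independent-
#' observations evidence rule is exercisable.
#'
#' @param sim a [simulate_family()] result.
#' @param config configuration (defaults to the one inside `sim`).
#' @return data frame of class `clone_library`: `clone_id`, `animal`,
#'   `gene` (true source gene), `pcr_batch`, `allele_true`, `event_true`
#'   (canonical event key, `""` for constitutive), `n_errors`, `seq`.
#' @export
simulate_clone_library <- function(sim, config = sim$config) {
  cfg <- config
  set.seed(cfg$seed + 1L)
  ped <- sim$pedigree
  genes <- sim$truth$gene_ids
  spectrum <- cfg$as_spectrum
  rows <- vector("list", nrow(ped) * length(genes))
  ri <- 0L
  # per-gene cache of event transcripts per allele
  cache <- new.env(parent = emptyenv())
  tx <- function(g, allele_idx, entry_idx) {
    key <- sprintf("%d.%d.%d", g, allele_idx, entry_idx)
    if (is.null(cache[[key]])) {
      entry <- if (entry_idx == 0L) NULL else spectrum[[entry_idx]]
      cache[[key]] <- .event_transcript(
        sim$models[[g]], sim$truth$allele_genomic[[g]][allele_idx], entry, cfg)
    }
    cache[[key]]
  }
  for (i in seq_len(nrow(ped))) {
    a <- ped$animal[i]
    for (g in seq_along(genes)) {
      depth <- cfg$clone_depth
      hap_alleles <- c(sim$truth$hap_sire[[a]][g], sim$truth$hap_dam[[a]][g])
      allele_pick <- hap_alleles[sample.int(2L, depth, replace = TRUE)]
      applicable <- which(vapply(spectrum, function(s) g %in% s$genes, logical(1)))
      pfun <- c(vapply(spectrum[applicable], `[[`, numeric(1), "freq"))
      u <- stats::runif(depth)
      ev_idx <- integer(depth)                         # 0 = constitutive
      if (length(applicable)) {
        cum <- cumsum(pfun)
        for (j in seq_len(depth)) {
          k <- which(u[j] < cum)
          if (length(k)) ev_idx[j] <- applicable[k[1L]]
        }
      }
      seqs <- character(depth); keys <- character(depth); nerr <- integer(depth)
      for (j in seq_len(depth)) {
        t <- tx(g, allele_pick[j], ev_idx[j])
        s <- t$seq
        ne <- stats::rbinom(1L, nchar(s), cfg$clone_error_rate)
        if (ne > 0L) {
          pos <- sample.int(nchar(s), ne)
          sv <- strsplit(s, "")[[1L]]
          sv[pos] <- vapply(sv[pos],
                            function(b) sample(setdiff(BASES, b), 1L), character(1))
          s <- paste(sv, collapse = "")
        }
        seqs[j] <- s; keys[j] <- t$key; nerr[j] <- ne
      }
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        clone_id = sprintf("%s.%s.c%02d", a, genes[g], seq_len(depth)),
        animal = a, gene = genes[g],
        pcr_batch = rep(c("PCR1", "PCR2"), length.out = depth),
        allele_true = names(sim$truth$alleles[[g]])[allele_pick],
        event_true = keys, n_errors = nerr, seq = seqs,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  class(out) <- c("clone_library", "data.frame")
  out
}

#' Sample splice-site training windows from a consensus model
#'
#' Emits fixed-width donor (9-nt: 3 exonic + 6 intronic) or acceptor (23-nt:
#' 20 intronic + 3 exonic) windows drawn from a position frequency model of
#' the mammalian consensus, for training the site scorers without any
#' external data. The generating frequency matrix is returned alongside the
#' windows so recovery can be checked.
#'
#' @param n number of windows.
#' @param type `"donor"` or `"acceptor"`.
#' @param seed integer seed.
#' @return list with `windows` (character vector) and `pwm` (4 x width
#'   generating frequency matrix, rows A,C,G,T).
#' @export
simulate_site_windows <- function(n, type = c("donor", "acceptor"), seed = 1L) {
  type <- match.arg(type)
  set.seed(seed)
  col <- function(dominant, p) {
    x <- rep((1 - p) / 3, 4); names(x) <- BASES
    x[dominant] <- p
    x
  }
  pyr <- c(A = 0.09, C = 0.36, G = 0.09, T = 0.46)
  if (type == "donor") {
    pwm <- cbind(col("C", 0.40), col("A", 0.60), col("G", 0.80),
                 col("G", 0.99), col("T", 0.99), col("A", 0.60),
                 col("A", 0.70), col("G", 0.80), col("T", 0.50))
  } else {
    pwm <- cbind(matrix(rep(pyr, 17), nrow = 4,
                        dimnames = list(BASES, NULL)),
                 col("C", 0.70), col("A", 0.99), col("G", 0.99),
                 col("G", 0.50), col("A", 0.30), col("T", 0.30))
  }
  rownames(pwm) <- BASES
  W <- ncol(pwm)
  windows <- vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(W), function(j) sample(BASES, 1L, prob = pwm[, j]),
                 character(1)), collapse = "")
  }, character(1))
  list(windows = windows, pwm = pwm)
}
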