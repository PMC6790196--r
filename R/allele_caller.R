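#' Assign clones to genes by k-mer anchor vote
#'
#' Computational stand-in for gene-specific PCR primers: each clone is
#' assigned to the gene model whose constitutive reference transcript shares
#' the most exact 31-mers with it. Ties (including zero votes everywhere)
#' leave the clone unassigned, with a warning.
#'
#' @param clones data frame with a `seq` column.
#' @param models named list of [gene_model()] objects.
#' @param k anchor length (default 31).
#' @return character vector of gene ids (NA where unassigned).
#' @export
assign_genes <- function(clones, models, k = 31L) {
  refs <- lapply(models, function(m) {
    s <- constitutive_mrna(m)
    unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
  })
  out <- vapply(clones$seq, function(s) {
    if (nchar(s) < k) return(NA_character_)
    km <- unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
    votes <- vapply(refs, function(r) sum(km %in% r), integer(1))
    top <- which(votes == max(votes))
    if (max(votes) == 0L || length(top) > 1L) NA_character_ else names(models)[top]
  }, character(1), USE.NAMES = FALSE)
  if (anyNA(out)) {
    warning(sprintf("%d clone(s) left unassigned (ambiguous or no gene match)",
                    sum(is.na(out))))
  }
  out
}

#' Group constitutive clones into exact-sequence clusters
#'
#' Only clones with a constitutive exon structure feed allele calling:
#' clones classified as alternatively spliced (or rejected by the aligner)
#' are excluded first, then the remainder are grouped by exact sequence
#' within each gene. No consensus-polishing is applied: clones carrying
#' sequencing errors form their own (typically unsupported) clusters and
#' are weeded out downstream by the evidence rule alone.
#'
#' @param clones clone data frame (`clone_id`, `animal`, `gene`,
#'   `pcr_batch`, `seq`). `gene` may come from the simulation truth or from
#'   [assign_genes()].
#' @param models named list of [gene_model()] objects.
#' @param classified optional precomputed [classify_transcripts()] result.
#' @return list of clusters, each a list with `gene`, `seq` and `support`
#'   (data frame `animal`, `pcr_batch`, `clone_id`), ordered by first
#'   observation.
#' @export
cluster_clones <- function(clones, models, classified = NULL) {
  if (is.null(classified)) classified <- classify_transcripts(clones, models)
  stopifnot(identical(classified$clone_id, clones$clone_id))
  keep <- classified$status == "ok" & classified$event_key == ""
  sub <- clones[keep, , drop = FALSE]
  if (nrow(sub) == 0L) return(list())
  cl_key <- paste(sub$gene, sub$seq, sep = "\r")
  first <- !duplicated(cl_key)
  order_keys <- cl_key[first]
  idx <- split(seq_len(nrow(sub)), factor(cl_key, levels = order_keys))
  lapply(idx, function(i) {
    list(gene = sub$gene[i[1L]], seq = sub$seq[i[1L]],
         support = data.frame(animal = sub$animal[i],
                              pcr_batch = sub$pcr_batch[i],
                              clone_id = sub$clone_id[i],
                              stringsAsFactors = FALSE))
  })
}

#' Validate alleles from clone clusters by the evidence rule
#'
#' A cluster is a validated allele when it holds at least two identical
#' clones that come from different animals or from independent PCRs of one
#' animal; all other clusters are retained as `singleton` (never genotyped).
#' Validated alleles receive IPD-style serial names `gene*NN`, assigned per
#' gene by first-observation order with a lexicographic tie-break on
#' sequence, so naming is stable across runs given identical input order.
#'
#' @param clusters a [cluster_clones()] result.
#' @return list of `allele_call` objects: `gene`, `allele_name` (NA for
#'   singletons), `seq`, `status`, `support`.
#' @export
call_alleles <- function(clusters) {
  if (length(clusters) == 0L) return(list())
  validated <- vapply(clusters, function(cl) {
    s <- cl$support
    nrow(s) >= 2L && length(unique(paste(s$animal, s$pcr_batch, sep = "\r"))) >= 2L
  }, logical(1))
  calls <- vector("list", length(clusters))
  genes <- vapply(clusters, `[[`, character(1), "gene")
  for (g in unique(genes)) {
    vi <- which(validated & genes == g)
    vi <- vi[order(vi, vapply(clusters[vi], `[[`, character(1), "seq"))]
    serial <- stats::setNames(seq_along(vi), vi)
    for (j in seq_along(vi)) {
      i <- vi[j]
      calls[[i]] <- structure(
        list(gene = g, allele_name = sprintf("%s*%02d", g, j),
             seq = clusters[[i]]$seq, status = "validated",
             support = clusters[[i]]$support),
        class = "allele_call")
    }
  }
  for (i in which(!validated)) {
    calls[[i]] <- structure(
      list(gene = genes[i], allele_name = NA_character_,
           seq = clusters[[i]]$seq, status = "singleton",
           support = clusters[[i]]$support),
      class = "allele_call")
  }
  calls
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf("<allele_call> %s (%s): %d supporting clone(s)\n",
              ifelse(is.na(x$allele_name), sprintf("%s singleton", x$gene),
                     x$allele_name),
              x$status, nrow(x$support)))
  invisible(x)
}

#' Summary table of allele calls
#' @param calls a [call_alleles()] result.
#' @return data frame: gene, allele_name, status, n_clones, n_animals,
#'   n_independent (distinct animal x batch combinations).
#' @export
allele_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) {
    data.frame(gene = x$gene, allele_name = x$allele_name, status = x$status,
               n_clones = nrow(x$support),
               n_animals = length(unique(x$support$animal)),
               n_independent = length(unique(paste(x$support$animal,
                                                   x$support$pcr_batch))),
               stringsAsFactors = FALSE)
  }))
}

#' Derive per-animal genotypes from validated alleles
#'
#' For each animal and gene, the set of validated alleles supported by that
#' animal's own clones. Singletons never enter a genotype. More than two
#' validated alleles for one animal and gene indicate contamination or a
#' collapsed paralog and raise an error rather than being silently
#' truncated.
#'
#' @param calls a [call_alleles()] result.
#' @return data frame: `animal`, `gene`, `allele1`, `allele2` (NA for
#'   homozygotes), sorted by animal and gene.
#' @export
genotype_animals <- function(calls) {
  validated <- Filter(function(x) x$status == "validated", calls)
  rows <- list()
  for (x in validated) {
    for (a in unique(x$support$animal)) {
      rows[[length(rows) + 1L]] <- data.frame(
        animal = a, gene = x$gene, allele = x$allele_name,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(animal = character(0), gene = character(0),
                      allele1 = character(0), allele2 = character(0)))
  }
  long <- unique(do.call(rbind, rows))
  out <- list()
  for (key in unique(paste(long$animal, long$gene, sep = "\r"))) {
    part <- strsplit(key, "\r")[[1L]]
    al <- sort(long$allele[long$animal == part[1L] & long$gene == part[2L]])
    if (length(al) > 2L) {
      stop(sprintf(
        "genotype error: %d validated alleles of %s in animal %s (contamination or collapsed paralogs): %s",
        length(al), part[2L], part[1L], paste(al, collapse = ", ")))
    }
    out[[length(out) + 1L]] <- data.frame(
      animal = part[1L], gene = part[2L], allele1 = al[1L],
      allele2 = if (length(al) == 2L) al[2L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[order(out$animal, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
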