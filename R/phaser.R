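#' Deduce multi-gene haplotypes from genotype co-segregation in a pedigree
#'
#' Exact search for the phase assignment of all animals in each family that
#' explains every diploid genotype by Mendelian transmission of whole
#' multi-gene haplotypes, under a zero-recombination prior between the
#' linked genes. Founder phases are enumerated depth-first with constraint
#' propagation down the pedigree and branch-and-bound on the number of
#' events (inter-gene recombinations or de-novo mutations) required; among
#' assignments with minimal events, the one with the fewest distinct
#' haplotypes is returned, with remaining ties broken by the
#' lexicographically smallest label sequence (ties are counted in the
#' metadata). Untyped animals participate as unconstrained transmitters:
#' their haplotypes are inferred (possibly partially) from their relatives.
#'
#' Families in this domain are small (typically under 20 animals), so the
#' exact search is practical and complete: whenever a zero-event assignment
#' exists it is found.
#'
#' @param pedigree data frame with columns `animal`, `sire`, `dam` (NA for
#'   founders) and optionally `family` (connected components are phased
#'   independently; derived automatically when absent).
#' @param genotypes data frame with columns `animal`, `gene`, `allele1`,
#'   `allele2` (NA `allele2` for homozygotes; animals/genes absent are
#'   untyped).
#' @param genes ordered character vector of gene ids defining the haplotype
#'   tuple (and the recombination intervals). Default: sorted unique genes.
#' @param max_events maximum total events before declaring a Mendelian
#'   inconsistency.
#' @param node_budget search-node cap (guards degenerate inputs).
#' @return list of class `phase_result`: `assignments` (animal, family,
#'   hap_sire, hap_dam labels), `haplotypes` (family, label, one column per
#'   gene), `events` (child, parent, type, detail), `metadata` (per family:
#'   events cost, number of tied optimal assignments).
#' @export
phase_family <- function(pedigree, genotypes, genes = NULL,
                         max_events = 4L, node_budget = 5e5) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  if (is.null(genes)) genes <- sort(unique(genotypes$gene))
  if (is.null(pedigree$family)) {
    pedigree$family <- .pedigree_components(pedigree)
  }
  assignments <- list(); haps_out <- list(); events_out <- list(); meta <- list()
  for (f in unique(pedigree$family)) {
    ped <- pedigree[pedigree$family == f, , drop = FALSE]
    res <- .phase_one_family(ped, genotypes, genes, max_events, node_budget)
    labels <- res$labels
    assignments[[length(assignments) + 1L]] <- data.frame(
      animal = res$order, family = f,
      hap_sire = labels$per_animal[, 1L], hap_dam = labels$per_animal[, 2L],
      stringsAsFactors = FALSE)
    ht <- data.frame(family = f, label = labels$label_names,
                     stringsAsFactors = FALSE)
    for (gi in seq_along(genes)) ht[[genes[gi]]] <- labels$tuples[, gi]
    haps_out[[length(haps_out) + 1L]] <- ht
    if (length(res$events)) {
      events_out[[length(events_out) + 1L]] <- cbind(
        family = f, do.call(rbind, lapply(res$events, as.data.frame)))
    }
    meta[[as.character(f)]] <- list(cost = res$cost, n_optimal = res$n_ties)
  }
  structure(list(
    assignments = do.call(rbind, assignments),
    haplotypes = do.call(rbind, haps_out),
    events = if (length(events_out)) do.call(rbind, events_out) else
      data.frame(family = character(0), child = character(0),
                 parent = character(0), type = character(0),
                 detail = character(0)),
    genes = genes, metadata = meta), class = "phase_result")
}

#' @export
print.phase_result <- function(x, ...) {
  cat(sprintf("<phase_result> %d animals, %d haplotypes, %d event(s)\n",
              nrow(x$assignments), nrow(x$haplotypes), nrow(x$events)))
  invisible(x)
}

.pedigree_components <- function(ped) {
  n <- nrow(ped)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  union_ <- function(i, j) { comp[find(i)] <<- find(j) }
  for (i in seq_len(n)) {
    for (p in c(ped$sire[i], ped$dam[i])) {
      if (!is.na(p)) {
        j <- match(p, ped$animal)
        if (!is.na(j)) union_(i, j)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Exact DFS phasing of one family. Haplotypes are integer vectors over the
# gene order (NA = unconstrained); writes into untyped slots are unified
# in place and undone on backtrack.
.phase_one_family <- function(ped, genotypes, genes, max_events, node_budget) {
  G <- length(genes)
  # allele coding per gene
  code <- lapply(genes, function(g) {
    sort(unique(stats::na.omit(c(genotypes$allele1[genotypes$gene == g],
                                 genotypes$allele2[genotypes$gene == g]))))
  })
  names(code) <- genes
  geno_of <- function(a) {
    m <- matrix(NA_integer_, G, 2L)
    sub <- genotypes[genotypes$animal == a, , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      gi <- match(sub$gene[r], genes)
      if (is.na(gi)) next
      a1 <- match(sub$allele1[r], code[[gi]])
      a2 <- if (is.na(sub$allele2[r])) a1 else match(sub$allele2[r], code[[gi]])
      m[gi, ] <- sort(c(a1, a2))
    }
    m
  }
  # topological order: founders (or parent-outside) first
  ids <- ped$animal
  placed <- rep(FALSE, nrow(ped))
  order_idx <- integer(0)
  parent_in <- function(p) !is.na(p) && p %in% ids
  is_founder <- !vapply(ped$sire, parent_in, logical(1)) |
    !vapply(ped$dam, parent_in, logical(1))
  while (length(order_idx) < nrow(ped)) {
    ready <- which(!placed & (is_founder |
      (vapply(ped$sire, function(p) is.na(p) || placed[match(p, ids)] %in% TRUE, logical(1)) &
       vapply(ped$dam, function(p) is.na(p) || placed[match(p, ids)] %in% TRUE, logical(1)))))
    if (length(ready) == 0L) stop("pedigree is cyclic")
    order_idx <- c(order_idx, ready[1L]); placed[ready[1L]] <- TRUE
  }
  ord <- ids[order_idx]
  geno <- lapply(ord, geno_of); names(geno) <- ord
  founder <- is_founder[order_idx]
  sire_of <- ped$sire[order_idx]; dam_of <- ped$dam[order_idx]

  env <- new.env(parent = emptyenv())
  env$haps <- stats::setNames(vector("list", length(ord)), ord)
  env$best <- NULL; env$best_key <- NULL; env$n_ties <- 0L
  env$nodes <- 0L; env$deepest <- 0L
  env$events <- list()

  label_solution <- function(haps) {
    keys <- character(0); per_animal <- matrix("", length(ord), 2L)
    tuples <- list()
    for (i in seq_along(ord)) {
      for (h in 1:2) {
        tup <- haps[[i]][[h]]
        key <- paste(tup, collapse = ",")
        j <- match(key, keys)
        if (is.na(key) || is.na(j)) { keys <- c(keys, key); j <- length(keys)
          tuples[[j]] <- tup }
        per_animal[i, h] <- letters[(j - 1L) %% 26L + 1L]
        if (j > 26L) per_animal[i, h] <- paste0(per_animal[i, h], (j - 1L) %/% 26L)
      }
    }
    list(per_animal = per_animal,
         label_names = vapply(seq_along(keys), function(j) {
           l <- letters[(j - 1L) %% 26L + 1L]
           if (j > 26L) paste0(l, (j - 1L) %/% 26L) else l
         }, character(1)),
         tuples = do.call(rbind, lapply(tuples, function(t) {
           vapply(seq_len(G), function(gi) {
             if (is.na(t[gi])) NA_character_ else code[[gi]][t[gi]]
           }, character(1))
         })),
         key = paste(per_animal, collapse = ""))
  }

  record <- function(cost) {
    haps_copy <- lapply(env$haps, function(h) list(h[[1L]], h[[2L]]))
    lab <- label_solution(haps_copy)
    cand <- list(cost = cost, haps = haps_copy, labels = lab,
                 n_labels = length(lab$label_names),
                 events = env$events)
    better <- is.null(env$best) ||
      cost < env$best$cost ||
      (cost == env$best$cost && cand$n_labels < env$best$n_labels) ||
      (cost == env$best$cost && cand$n_labels == env$best$n_labels &&
         lab$key < env$best$labels$key)
    if (better) {
      if (!is.null(env$best) && cost == env$best$cost &&
          cand$n_labels == env$best$n_labels) env$n_ties <- env$n_ties + 1L
      else env$n_ties <- 1L
      env$best <- cand
    } else if (cost == env$best$cost && cand$n_labels == env$best$n_labels &&
               lab$key != env$best$labels$key) {
      env$n_ties <- env$n_ties + 1L
    }
  }

  # candidate gametes of a parent, cheapest first
  candidates <- function(pi) {
    h <- env$haps[[pi]]
    out <- list(list(src = c(1L, rep(1L, G - 1L)), cost = 0L, ev = NULL),
                list(src = c(2L, rep(2L, G - 1L)), cost = 0L, ev = NULL))
    out[[1L]]$src <- rep(1L, G); out[[2L]]$src <- rep(2L, G)
    if (G > 1L) {
      for (k in seq_len(G - 1L)) for (s in 1:2) {
        out[[length(out) + 1L]] <- list(
          src = c(rep(s, k), rep(3L - s, G - k)), cost = 1L,
          ev = list(type = "recombination", parent = ord[pi],
                    detail = sprintf("interval %d (%s|%s)", k, genes[k], genes[k + 1L])))
      }
    }
    for (mg in seq_len(G)) for (s in 1:2) {
      out[[length(out) + 1L]] <- list(
        src = rep(s, G), cost = 1L, free = mg,
        ev = list(type = "mutation", parent = ord[pi],
                  detail = sprintf("gene %s", genes[mg])))
    }
    out
  }

  # resolve one child's genotype against a (sire gamete, dam gamete) pair;
  # branches over per-gene orientation where both fit. Returns via continuation.
  resolve <- function(ci, cs, cd, si, di, gi, h1, h2, writes, cont) {
    if (gi > G) { cont(h1, h2, writes); return(invisible()) }
    gm <- geno[[ci]][gi, ]
    src_s <- cs$src[gi]; src_d <- cd$src[gi]
    vs <- env$haps[[si]][[src_s]][gi]
    vd <- env$haps[[di]][[src_d]][gi]
    free_s <- !is.null(cs$free) && cs$free == gi
    free_d <- !is.null(cd$free) && cd$free == gi
    if (is.na(gm[1L])) {                      # untyped gene: values flow through
      h1[gi] <- if (free_s) NA_integer_ else vs
      h2[gi] <- if (free_d) NA_integer_ else vd
      resolve(ci, cs, cd, si, di, gi + 1L, h1, h2, writes, cont)
      return(invisible())
    }
    try_orient <- function(need_s, need_d) {
      w <- list()
      ok_s <- if (free_s) TRUE else if (is.na(vs)) {
        env$haps[[si]][[src_s]][gi] <- need_s
        w[[length(w) + 1L]] <- list(si, src_s, gi); TRUE
      } else vs == need_s
      if (!ok_s) { for (u in rev(w)) env$haps[[u[[1L]]]][[u[[2L]]]][u[[3L]]] <- NA_integer_
        return(invisible()) }
      ok_d <- if (free_d) TRUE else if (is.na(vd)) {
        env$haps[[di]][[src_d]][gi] <- need_d
        w[[length(w) + 1L]] <- list(di, src_d, gi); TRUE
      } else vd == need_d
      if (!ok_d) { for (u in rev(w)) env$haps[[u[[1L]]]][[u[[2L]]]][u[[3L]]] <- NA_integer_
        return(invisible()) }
      h1[gi] <- need_s; h2[gi] <- need_d
      resolve(ci, cs, cd, si, di, gi + 1L, h1, h2, c(writes, w), cont)
      for (u in rev(w)) env$haps[[u[[1L]]]][[u[[2L]]]][u[[3L]]] <- NA_integer_
      invisible()
    }
    try_orient(gm[1L], gm[2L])
    if (gm[1L] != gm[2L]) try_orient(gm[2L], gm[1L])
    invisible()
  }

  solve <- function(i, cost) {
    env$nodes <- env$nodes + 1L
    if (env$nodes > node_budget) {
      stop("phasing search budget exceeded (raise node_budget)")
    }
    if (!is.null(env$best) && cost > env$best$cost) return(invisible())
    if (i > length(ord)) { record(cost); return(invisible()) }
    env$deepest <- max(env$deepest, i)
    if (founder[i]) {
      gm <- geno[[i]]
      het <- which(!is.na(gm[, 1L]) & gm[, 1L] != gm[, 2L])
      base1 <- ifelse(is.na(gm[, 1L]), NA_integer_, gm[, 1L])
      base2 <- ifelse(is.na(gm[, 1L]), NA_integer_, gm[, 2L])
      n_branch <- if (length(het) > 1L) length(het) - 1L else 0L
      flips <- if (n_branch == 0L) list(logical(0)) else {
        do.call(expand.grid, rep(list(c(FALSE, TRUE)), n_branch)) |>
          apply(1L, as.logical, simplify = FALSE)
      }
      for (fl in flips) {
        h1 <- base1; h2 <- base2
        if (length(het) > 1L) {
          flip_genes <- het[-1L][fl]
          h1[flip_genes] <- base2[flip_genes]
          h2[flip_genes] <- base1[flip_genes]
        }
        env$haps[[i]] <- list(h1, h2)
        solve(i + 1L, cost)
        env$haps[i] <- list(NULL)
      }
      return(invisible())
    }
    si <- match(sire_of[i], ord); di <- match(dam_of[i], ord)
    cands_s <- candidates(si); cands_d <- candidates(di)
    for (cs in cands_s) for (cd in cands_d) {
      extra <- cs$cost + cd$cost
      if (cost + extra > env$cap) next
      if (!is.null(env$best) && cost + extra > env$best$cost) next
      ev_save <- env$events
      if (!is.null(cs$ev)) env$events <- c(env$events,
        list(c(list(child = ord[i]), cs$ev)))
      if (!is.null(cd$ev)) env$events <- c(env$events,
        list(c(list(child = ord[i]), cd$ev)))
      resolve(i, cs, cd, si, di, 1L,
              rep(NA_integer_, G), rep(NA_integer_, G), list(),
              function(h1, h2, writes) {
                env$haps[[i]] <- list(h1, h2)
                solve(i + 1L, cost + extra)
                env$haps[i] <- list(NULL)
              })
      env$events <- ev_save
    }
    invisible()
  }

  # iterative deepening on event count: zero-event assignments are found
  # without ever exploring event branches
  for (cap in 0:max_events) {
    env$cap <- cap
    solve(1L, 0L)
    if (!is.null(env$best)) break
  }
  if (is.null(env$best)) {
    ci <- min(env$deepest + 0L, length(ord))
    stop(sprintf(
      "Mendelian inconsistency: no phase assignment (within %d events) explains trio child=%s sire=%s dam=%s",
      max_events, ord[ci], sire_of[ci], dam_of[ci]))
  }
  list(order = ord, labels = env$best$labels, cost = env$best$cost,
       events = env$best$events, n_ties = env$n_ties)
}

#' Co-segregation of deduced haplotypes with an external haplotype labelling
#'
#' Families in these colonies are typically also typed for their MHC
#' haplotypes; frequent co-transmission of a gene-cluster haplotype with one
#' MHC haplotype corroborates the cluster's location. For every
#' parent-to-child transmission, the transmitted cluster haplotype (known
#' from the phase assignment) is paired with the external label transmitted
#' by the same parent; for each parental haplotype the modal pairing is
#' taken as the chromosomal phase, and transmissions deviating from it are
#' counted as discordant (e.g. a crossover between the cluster and the
#' external locus). Transmissions whose external label cannot be assigned
#' to a unique parent are excluded with a warning.
#'
#' @param phased a [phase_family()] result.
#' @param pedigree the pedigree used for phasing.
#' @param external_labels data frame `animal`, `ext1`, `ext2`.
#' @return list: `pairs` (child, parent, haplotype, external),
#'   `table` (counts of haplotype x external pairings),
#'   `concordant`, `discordant`, `excluded`.
#' @export
cosegregation_table <- function(phased, pedigree, external_labels) {
  asn <- phased$assignments
  ext <- stats::setNames(
    lapply(seq_len(nrow(external_labels)), function(i) {
      c(external_labels$ext1[i], external_labels$ext2[i])
    }), external_labels$animal)
  pairs <- list(); excluded <- 0L
  for (i in seq_len(nrow(pedigree))) {
    child <- pedigree$animal[i]
    sire <- pedigree$sire[i]; dam <- pedigree$dam[i]
    if (is.na(sire) || is.na(dam)) next
    if (!child %in% asn$animal || !all(c(sire, dam) %in% asn$animal)) next
    if (!all(c(child, sire, dam) %in% names(ext))) {
      warning(sprintf("animal missing from external labelling around %s; transmission excluded", child))
      excluded <- excluded + 1L
      next
    }
    ce <- ext[[child]]; se <- ext[[sire]]; de <- ext[[dam]]
    o1 <- ce[1L] %in% se && ce[2L] %in% de
    o2 <- ce[2L] %in% se && ce[1L] %in% de
    if (o1 == o2) {                     # ambiguous or impossible
      warning(sprintf("external transmission around %s is %s; excluded",
                      child, if (o1) "ambiguous" else "inconsistent"))
      excluded <- excluded + 1L
      next
    }
    from_sire_ext <- if (o1) ce[1L] else ce[2L]
    from_dam_ext <- if (o1) ce[2L] else ce[1L]
    row <- asn[asn$animal == child, ]
    # transmissions from a haplotype-homozygous parent are uninformative:
    # the transmitted chromosome cannot be identified from the cluster side
    informative <- function(p) {
      pr <- asn[asn$animal == p, ]
      nrow(pr) == 1L && pr$hap_sire != pr$hap_dam
    }
    if (informative(sire)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        child = child, parent = sire, haplotype = row$hap_sire,
        external = from_sire_ext, stringsAsFactors = FALSE)
    } else excluded <- excluded + 1L
    if (informative(dam)) {
      pairs[[length(pairs) + 1L]] <- data.frame(
        child = child, parent = dam, haplotype = row$hap_dam,
        external = from_dam_ext, stringsAsFactors = FALSE)
    } else excluded <- excluded + 1L
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(child = character(0), parent = character(0),
               haplotype = character(0), external = character(0))
  concordant <- 0L; discordant <- 0L
  if (nrow(pairs)) {
    key <- paste(pairs$parent, pairs$haplotype)
    for (k in unique(key)) {
      exts <- pairs$external[key == k]
      modal <- names(sort(table(exts), decreasing = TRUE))[1L]
      concordant <- concordant + sum(exts == modal)
      discordant <- discordant + sum(exts != modal)
    }
  }
  list(pairs = pairs,
       table = if (nrow(pairs)) table(pairs$haplotype, pairs$external) else
         table(character(0)),
       concordant = concordant, discordant = discordant, excluded = excluded)
}
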