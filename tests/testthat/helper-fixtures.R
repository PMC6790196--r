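# Shared fixtures and independent oracles. Everything is generated in code;
# nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# small error-free cohort reused within a test file
small_sim <- function(seed = 5L, ...) {
  key <- paste("sim", seed, paste(c(...), collapse = "_"))
  if (is.null(.fixture_env[[key]])) {
    cfg <- cohort_config(seed = seed, clone_error_rate = 0,
                         generations = 3L, n_families = 1L, ...)
    .fixture_env[[key]] <- simulate_family(cfg)
  }
  .fixture_env[[key]]
}

# independent closed form for the chain-structured maximum-entropy model:
# P(w) = p1(x1) * prod_i p(x_i, x_{i+1}) / p_i(x_i), computed directly from
# the pseudocounted empirical pair marginals
chain_log_prob <- function(window, windows, pseudocount = 0.5) {
  bases <- c("A", "C", "G", "T")
  idx <- do.call(rbind, lapply(strsplit(windows, ""), match, bases))
  n <- nrow(idx); W <- ncol(idx)
  emp2 <- lapply(seq_len(W - 1L), function(i) {
    (as.matrix(table(factor(idx[, i], 1:4), factor(idx[, i + 1L], 1:4))) +
       pseudocount) / (n + 16 * pseudocount)
  })
  b <- match(strsplit(window, "")[[1L]], bases)
  lp <- log(sum(emp2[[1L]][b[1L], ]))
  for (i in seq_len(W - 1L)) {
    lp <- lp + log(emp2[[i]][b[i], b[i + 1L]] / sum(emp2[[i]][b[i], ]))
  }
  lp
}

# brute-force minimum-evolution tree: enumerate all unrooted topologies,
# fit OLS branch lengths via the edge-path incidence matrix, return the
# topology minimizing total length
brute_force_me_tree <- function(d) {
  labs <- rownames(d)
  n <- length(labs)
  tops <- phangorn::allTrees(n, rooted = FALSE, tip.label = labs)
  pairs <- t(combn(n, 2L))
  dv <- d[pairs]
  best <- NULL; best_len <- Inf
  for (ti in seq_along(tops)) {
    tr <- tops[[ti]]                   # [[ restores the shared tip labels
    below <- lapply(tr$edge[, 2L], function(node) {
      unlist(phangorn::Descendants(tr, node, "tips"))
    })
    A <- vapply(below, function(bt) {
      xor(pairs[, 1L] %in% bt, pairs[, 2L] %in% bt) + 0
    }, numeric(nrow(pairs)))
    len <- sum(stats::lm.fit(A, dv)$coefficients, na.rm = TRUE)
    if (len < best_len - 1e-12) { best_len <- len; best <- tr }
  }
  # normalize edge ordering (allTrees emits postorder, which trips ape)
  stats::reorder(best)
}

# distance matrix from the cophenetic distances of a random additive tree
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.5, 3))
  d <- ape::cophenetic.phylo(tr)
  d[sort(rownames(d)), sort(rownames(d))]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(t1, t2, check.labels = TRUE) == 0
}

# truth accessors shared by caller/phaser tests
truth_allele_seqs <- function(sim) {
  gt <- true_genotypes(sim)
  unique(unlist(lapply(seq_along(sim$models), function(g) {
    a <- sim$truth$alleles[[g]]
    gid <- names(sim$models)[g]
    carried <- unique(c(gt$allele1[gt$gene == gid], gt$allele2[gt$gene == gid]))
    unname(a[names(a) %in% carried])
  })))
}

validated_seqs <- function(calls) {
  vapply(Filter(function(x) x$status == "validated", calls),
         `[[`, character(1), "seq")
}

# per-animal multiset of true haplotype allele tuples
truth_haplotype_strings <- function(sim, animal) {
  sort(vapply(list(sim$truth$hap_sire[[animal]], sim$truth$hap_dam[[animal]]),
              function(h) {
                paste(vapply(seq_along(h), function(g)
                  names(sim$truth$alleles[[g]])[h[g]], character(1)),
                  collapse = "|")
              }, character(1)))
}
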