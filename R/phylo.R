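#' Pairwise distances between aligned sequences
#'
#' Computes p-distances (mismatch fraction) or Kimura two-parameter (K2P)
#' distances over an alignment, with pairwise deletion: for each sequence
#' pair, positions where either sequence has a gap, `N` or other ambiguity
#' are removed for that pair only. K2P is
#' `-1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` with `P` and `Q` the transition
#' and transversion fractions; a saturated pair (non-positive log argument)
#' is an error naming the pair.
#'
#' @param alignment named character vector of equal-length aligned sequences
#'   (or a character matrix with one row per sequence).
#' @param model `"p"` or `"K2P"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
pairwise_distances <- function(alignment, model = c("p", "K2P")) {
  model <- match.arg(model)
  if (is.matrix(alignment)) {
    mat <- toupper(alignment)
  } else {
    if (length(unique(nchar(alignment))) != 1L) {
      stop("sequences are not aligned (unequal lengths)")
    }
    mat <- do.call(rbind, strsplit(toupper(alignment), ""))
    rownames(mat) <- names(alignment)
  }
  n <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("seq%d", seq_len(n))
  labs <- rownames(mat)
  purine <- c("A", "G")
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- mat[i, ] %in% BASES & mat[j, ] %in% BASES
    a <- mat[i, ok]; b <- mat[j, ok]
    L <- length(a)
    if (L == 0L) stop(sprintf("no comparable positions between %s and %s",
                              labs[i], labs[j]))
    if (model == "p") {
      d[i, j] <- d[j, i] <- mean(a != b)
    } else {
      diffs <- a != b
      ti <- diffs & ((a %in% purine) == (b %in% purine))
      P <- sum(ti) / L
      Q <- sum(diffs & !ti) / L
      if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
        stop(sprintf("K2P distance saturated for pair %s / %s", labs[i], labs[j]))
      }
      d[i, j] <- d[j, i] <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
  }
  d
}

#' Neighbour-joining tree
#'
#' Canonical Saitou-Nei agglomeration from a distance matrix. Ties in the
#' Q criterion are broken deterministically by the lexicographically
#' smallest pair of cluster labels (a cluster is labelled by its smallest
#' member taxon). Negative branch lengths are clamped to zero and the total
#' clamped deficit recorded as an attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return an [ape::phylo] unrooted tree; attribute `clamped` holds the
#'   total negative-branch-length deficit.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    stop("invalid distance matrix (asymmetric or nonzero diagonal)")
  }
  labs <- rownames(d)
  newick <- labs                 # growing subtree strings
  minlab <- labs                 # deterministic tie-break label per cluster
  act <- seq_len(n)
  D <- d
  clamped <- 0
  clamp <- function(x) { clamped <<- clamped + sum(pmin(x, 0)); pmax(x, 0) }
  while (length(act) > 3L) {
    m <- length(act)
    Dm <- D[act, act]
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pair_labs <- apply(cand, 1L, function(ij) {
      paste(sort(minlab[act[ij]]), collapse = "\r")
    })
    best <- cand[order(pair_labs)[1L], ]
    i <- act[best[1L]]; j <- act[best[2L]]
    vi <- Dm[best[1L], best[2L]] / 2 +
      (r[best[1L]] - r[best[2L]]) / (2 * (m - 2))
    vj <- Dm[best[1L], best[2L]] - vi
    vi <- clamp(vi); vj <- clamp(vj)
    newk <- sprintf("(%s:%.10g,%s:%.10g)", newick[i], vi, newick[j], vj)
    dnew <- (D[i, act] + D[j, act] - D[i, j]) / 2
    D[i, act] <- dnew; D[act, i] <- dnew
    D[i, i] <- 0
    newick[i] <- newk
    minlab[i] <- min(minlab[i], minlab[j])
    act <- setdiff(act, j)
  }
  a <- act[1L]; b <- act[2L]; c_ <- act[3L]
  la <- clamp((D[a, b] + D[a, c_] - D[b, c_]) / 2)
  lb <- clamp((D[a, b] + D[b, c_] - D[a, c_]) / 2)
  lc <- clamp((D[a, c_] + D[b, c_] - D[a, b]) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 newick[a], la, newick[b], lb, newick[c_], lc)
  tree <- ape::read.tree(text = txt)
  attr(tree, "clamped") <- -clamped
  tree
}

#' Bootstrap support for the neighbour-joining tree of an alignment
#'
#' Builds the NJ tree of the full alignment, then resamples alignment
#' columns with replacement `reps` times, rebuilds the NJ tree of each
#' replicate, and reports for every internal edge of the original tree the
#' percentage of replicates containing the same bipartition. Supports are
#' stored as node labels, the standard Newick dialect.
#'
#' @param alignment named character vector of aligned sequences.
#' @param reps bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param model distance model passed to [pairwise_distances()].
#' @return list of class `tree_with_support`: `tree` (phylo, node labels =
#'   support %), `supports`, `reps`.
#' @export
bootstrap_support <- function(alignment, reps = 1000L, seed = 1L,
                              model = "K2P") {
  set.seed(seed)
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- names(alignment)
  main <- nj_tree(pairwise_distances(mat, model))
  L <- ncol(mat)
  reptrees <- vector("list", reps)
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    reptrees[[r]] <- nj_tree(pairwise_distances(mat[, cols, drop = FALSE], model))
  }
  class(reptrees) <- "multiPhylo"
  counts <- ape::prop.clades(main, reptrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- round(100 * counts / reps, 1)
  main$node.label <- as.character(support)
  # bipartition table: rooting every replicate at the same reference tip
  # turns each internal bipartition into a clade prop.part can count
  ref <- main$tip.label[1L]
  rooted_reps <- lapply(reptrees, function(tr) {
    ape::root(tr, outgroup = ref, resolve.root = TRUE)
  })
  class(rooted_reps) <- "multiPhylo"
  structure(list(tree = main, supports = support, reps = reps,
                 partitions = ape::prop.part(rooted_reps), ref_tip = ref),
            class = "tree_with_support")
}

#' Bootstrap support of one bipartition
#'
#' Looks a tip set up directly in the replicate bipartition table of a
#' [bootstrap_support()] result: the percentage of replicate trees in which
#' these tips (or equivalently their complement) form one side of an
#' internal edge.
#'
#' @param x a [bootstrap_support()] result.
#' @param tips tip labels of the clade of interest.
#' @return support percentage (0 when the bipartition never occurs).
#' @export
clade_support <- function(x, tips) {
  pp <- x$partitions
  labels <- attr(pp, "labels")
  idx <- sort(match(tips, labels))
  if (anyNA(idx)) stop("unknown tip label")
  comp <- sort(setdiff(seq_along(labels), idx))
  # replicates are rooted at ref_tip: the bipartition side away from the
  # reference tip is the side that appears as a clade
  ref_i <- match(x$ref_tip, labels)
  side <- if (ref_i %in% idx) comp else idx
  counts <- attr(pp, "number")
  for (i in seq_along(pp)) {
    if (identical(sort(pp[[i]]), side)) {
      return(round(100 * counts[i] / x$reps, 1))
    }
  }
  0
}

#' @export
print.tree_with_support <- function(x, ...) {
  cat(sprintf("<tree_with_support> %d tips, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$reps))
  invisible(x)
}

#' Simulate an ortholog-family alignment on a star-of-stars genealogy
#'
#' Emulates the evolution of a small multigene family across several
#' species: one ancestral sequence diverges into `n_genes` gene ancestors
#' (deep branches, `inter` expected substitutions per site each), each of
#' which then diverges into `n_species` orthologous tip sequences (shallow
#' branches, `intra` per site). Substitutions follow the Jukes-Cantor
#' process. When inter-gene divergence far exceeds intra-gene divergence,
#' each gene's tips form a clade, which is the clustering signature probed
#' in comparative studies of such families.
#'
#' @param n_genes,n_species family and species counts.
#' @param len alignment length in nt.
#' @param inter,intra branch lengths in expected substitutions per site.
#' @param seed integer seed.
#' @return named character vector (`gene<g>_sp<s>`).
#' @export
simulate_ortholog_alignment <- function(n_genes = 3L, n_species = 6L,
                                        len = 500L, inter = 0.3,
                                        intra = 0.02, seed = 1L) {
  set.seed(seed)
  evolve <- function(sv, t) {
    p <- 0.75 * (1 - exp(-4 * t / 3))
    hit <- stats::runif(length(sv)) < p
    sv[hit] <- vapply(sv[hit], function(b) sample(setdiff(BASES, b), 1L),
                      character(1))
    sv
  }
  root <- sample(BASES, len, replace = TRUE)
  out <- character(0)
  for (g in seq_len(n_genes)) {
    anc <- evolve(root, inter)
    for (s in seq_len(n_species)) {
      tip <- evolve(anc, intra)
      out[sprintf("gene%d_sp%d", g, s)] <- paste(tip, collapse = "")
    }
  }
  out
}

#' Test gene-wise monophyly in a tree
#'
#' @param tree a phylo object.
#' @param tips tip labels of the putative clade.
#' @return TRUE when the tips form a clade on the unrooted tree.
#' @export
is_clade <- function(tree, tips) {
  other <- setdiff(tree$tip.label, tips)
  if (length(other) == 0L) return(TRUE)
  rooted <- ape::root(tree, outgroup = other[1L], resolve.root = TRUE)
  ape::is.monophyletic(rooted, tips)
}

#' Write a supported tree to Newick
#'
#' @param x a [bootstrap_support()] result or phylo object.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_tree_file <- function(x, path) {
  tree <- if (inherits(x, "tree_with_support")) x$tree else x
  ape::write.tree(tree, file = path)
  invisible(path)
}
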