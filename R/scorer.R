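#' Train a position-weight-matrix splice-site model
#'
#' Per-position base frequencies with a pseudocount; a window scores the sum
#' of per-position log2 likelihood ratios against the background base
#' composition. With a zero pseudocount, positions with zero training
#' frequency score at a floor of -20 bits rather than -Inf, so comparisons
#' remain finite.
#'
#' Windows follow the common convention: donors are 9-mers (3 exonic + 6
#' intronic bases around the exon|intron boundary), acceptors 23-mers (20
#' intronic + 3 exonic). The trainer accepts any fixed width.
#'
#' @param windows character vector of equal-width training site windows
#'   (at least 10).
#' @param background named base frequencies (default uniform).
#' @param pseudocount added per cell (default 0.5).
#' @param site_type optional `"donor"` or `"acceptor"` tag.
#' @return list of class `site_model` with `kind = "pwm"`.
#' @export
train_pwm <- function(windows, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.5, site_type = NULL) {
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("width mismatch: training windows differ in length")
  if (length(windows) < 10L) stop("need at least 10 training sites")
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  freqs <- vapply(seq_len(W), function(j) {
    counts <- table(factor(mat[, j], levels = BASES))
    (as.numeric(counts) + pseudocount) / (length(windows) + 4 * pseudocount)
  }, numeric(4))
  rownames(freqs) <- BASES
  structure(list(kind = "pwm", site_type = site_type, width = W,
                 freqs = freqs, background = background[BASES], floor = -20),
            class = "site_model")
}

#' Score windows under a trained splice-site model
#'
#' Returns `sum_i log2 f_i(w_i) / bg(w_i)` for PWM models and
#' `log2 P(w) / P_bg(w)` for maximum-entropy models. Scores are comparative
#' only — they carry no absolute threshold and should only be compared
#' between related sites of the same type under the same model.
#'
#' @param model a [train_pwm()] or [train_maxent()] model.
#' @param windows character vector of windows of the model's width.
#' @return numeric scores in bits.
#' @export
score_windows <- function(model, windows) {
  W <- model$width
  if (any(nchar(windows) != W)) {
    stop(sprintf("width mismatch: model expects %d-nt windows", W))
  }
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  idx <- matrix(match(mat, BASES), nrow(mat))
  if (anyNA(idx)) stop("windows contain non-ACGT characters")
  bg_l2 <- log2(model$background)
  if (model$kind == "pwm") {
    lods <- log2(model$freqs)
    lods[!is.finite(lods)] <- model$floor
    lods <- sweep(lods, 1L, bg_l2)
    vapply(seq_len(nrow(idx)), function(r) {
      sum(lods[cbind(idx[r, ], seq_len(W))])
    }, numeric(1))
  } else {
    l1 <- model$lambda1                       # W x 4
    l2 <- model$lambda2                       # (W-1) x 4 x 4 or NULL
    vapply(seq_len(nrow(idx)), function(r) {
      b <- idx[r, ]
      lp <- sum(l1[cbind(seq_len(W), b)]) - model$logZ
      if (!is.null(l2)) {
        lp <- lp + sum(l2[cbind(seq_len(W - 1L), b[-W], b[-1L])])
      }
      lp / log(2) - sum(bg_l2[b])
    }, numeric(1))
  }
}

# forward-backward marginals of the chain-factorized exponential model
.maxent_marginals <- function(lambda1, lambda2, W) {
  N <- exp(lambda1)                           # W x 4 node weights
  Fwd <- matrix(0, W, 4L)
  Fwd[1L, ] <- N[1L, ]
  for (i in seq_len(W - 1L)) {
    E <- if (is.null(lambda2)) matrix(1, 4L, 4L) else exp(lambda2[i, , ])
    Fwd[i + 1L, ] <- (Fwd[i, ] %*% E) * N[i + 1L, ]
  }
  Z <- sum(Fwd[W, ])
  Bwd <- matrix(0, W, 4L)
  Bwd[W, ] <- 1
  for (i in rev(seq_len(W - 1L))) {
    E <- if (is.null(lambda2)) matrix(1, 4L, 4L) else exp(lambda2[i, , ])
    Bwd[i, ] <- E %*% (Bwd[i + 1L, ] * N[i + 1L, ])
  }
  singles <- Fwd * Bwd / Z
  pairs <- NULL
  if (!is.null(lambda2)) {
    pairs <- array(0, dim = c(W - 1L, 4L, 4L))
    for (i in seq_len(W - 1L)) {
      E <- exp(lambda2[i, , ])
      pairs[i, , ] <- outer(Fwd[i, ], Bwd[i + 1L, ] * N[i + 1L, ]) * E / Z
    }
  }
  list(singles = singles, pairs = pairs, logZ = log(Z))
}

#' Train a maximum-entropy splice-site model
#'
#' Fits the least-committed distribution over windows that matches the
#' empirical per-position base marginals (`order = "1"`) and additionally
#' all adjacent-position pair marginals (`order = "2-adjacent"`), by
#' generalized iterative scaling. Feature expectations under the current
#' model are computed by forward-backward dynamic programming over the
#' position chain, so the full 4^W sequence space is never enumerated.
#' With order-1 constraints only, the fitted distribution is the product of
#' the marginals and scores coincide with the PWM trained on the same data.
#'
#' @inheritParams train_pwm
#' @param order `"1"` or `"2-adjacent"`.
#' @param tol convergence threshold on the maximum absolute discrepancy
#'   between empirical and model marginals.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   final discrepancy.
#' @return list of class `site_model` with `kind = "maxent"`.
#' @export
train_maxent <- function(windows, order = c("1", "2-adjacent"),
                         background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                         pseudocount = 0.5, tol = 1e-8, max_iter = 10000L,
                         site_type = NULL) {
  order <- match.arg(order)
  W <- unique(nchar(windows))
  if (length(W) != 1L) stop("width mismatch: training windows differ in length")
  if (length(windows) < 10L) stop("need at least 10 training sites")
  n <- length(windows)
  mat <- do.call(rbind, strsplit(toupper(windows), ""))
  idx <- matrix(match(mat, BASES), n)
  emp1 <- t(vapply(seq_len(W), function(j) {
    (tabulate(idx[, j], 4L) + pseudocount) / (n + 4 * pseudocount)
  }, numeric(4)))
  emp2 <- NULL
  if (order == "2-adjacent" && W > 1L) {
    emp2 <- array(0, dim = c(W - 1L, 4L, 4L))
    for (i in seq_len(W - 1L)) {
      tab <- table(factor(idx[, i], 1:4), factor(idx[, i + 1L], 1:4))
      emp2[i, , ] <- (as.matrix(tab) + pseudocount) / (n + 16 * pseudocount)
    }
    # single-position targets must marginalize from the pair tables, or the
    # pseudocounted constraint set is infeasible and scaling cannot converge
    emp1 <- rbind(t(vapply(seq_len(W - 1L), function(i) rowSums(emp2[i, , ]),
                           numeric(4))),
                  colSums(emp2[W - 1L, , ]))
  }
  lambda1 <- matrix(0, W, 4L)
  lambda2 <- if (!is.null(emp2)) array(0, dim = c(W - 1L, 4L, 4L)) else NULL
  C <- W + if (!is.null(emp2)) W - 1L else 0L
  disc <- Inf
  for (it in seq_len(max_iter)) {
    m <- .maxent_marginals(lambda1, lambda2, W)
    disc <- max(abs(m$singles - emp1))
    if (!is.null(emp2)) disc <- max(disc, max(abs(m$pairs - emp2)))
    if (disc < tol) break
    lambda1 <- lambda1 + log(emp1 / m$singles) / C
    if (!is.null(emp2)) lambda2 <- lambda2 + log(emp2 / m$pairs) / C
  }
  if (disc >= tol) {
    stop(sprintf(
      "maximum-entropy training did not converge in %d iterations (max marginal discrepancy %.3g)",
      max_iter, disc))
  }
  m <- .maxent_marginals(lambda1, lambda2, W)
  structure(list(kind = "maxent", site_type = site_type, width = W,
                 order = order, lambda1 = lambda1, lambda2 = lambda2,
                 logZ = m$logZ, background = background[BASES],
                 marginals = m$singles, pair_marginals = m$pairs,
                 iterations = it, discrepancy = disc),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  cat(sprintf("<site_model> %s%s, width %d%s\n", x$kind,
              if (!is.null(x$site_type)) paste0(" (", x$site_type, ")") else "",
              x$width,
              if (x$kind == "maxent") sprintf(", order %s", x$order) else ""))
  invisible(x)
}

#' Extract a donor or acceptor window from a gene's genomic sequence
#'
#' Donor windows cover 3 exonic + 6 intronic bases around the annotated (or
#' alternative) exon end; acceptor windows 20 intronic + 3 exonic bases
#' around the exon start. Positions are 0-based: a donor position is the
#' half-open end of the exonic segment, an acceptor position its start.
#'
#' @param model a [gene_model()].
#' @param pos 0-based site position (see above).
#' @return character window.
#' @export
donor_window <- function(model, pos) {
  if (pos - 3L < 0L || pos + 6L > nchar(model$genomic_seq)) {
    stop("window extends past the sequence end")
  }
  substr(model$genomic_seq, pos - 2L, pos + 6L)
}

#' @rdname donor_window
#' @export
acceptor_window <- function(model, pos) {
  if (pos - 20L < 0L || pos + 3L > nchar(model$genomic_seq)) {
    stop("window extends past the sequence end")
  }
  substr(model$genomic_seq, pos - 19L, pos + 3L)
}

#' Score the actual versus alternative splice sites of an event
#'
#' For each classified event, extracts the constitutively used (actual) and
#' alternatively used site windows from the gene sequence and scores both
#' under each supplied site model, flagging which site each model favours.
#' For skip events the skipped exon's own acceptor/donor (actual) are
#' compared with the acceptor/donor of the retained flanking exons used by
#' the skip junction; for alternative-site events the annotated site is
#' compared with the shifted one; the paired 3'SS+5'SS class yields one
#' acceptor and one donor comparison against the host exon's own sites.
#' Scores carry no threshold: only the comparison between related sites is
#' meaningful.
#'
#' @param event a `splice_event` from [classify_events()].
#' @param model the [gene_model()].
#' @param site_models list of [train_pwm()]/[train_maxent()] models, each
#'   with `site_type` set to `"donor"` or `"acceptor"`.
#' @return data frame of class `site_comparison`: `event`, `site_type`,
#'   `kind`, `actual_pos`, `alt_pos`, `actual_score`, `alt_score`,
#'   `dominant` (`"actual"`, `"alternative"` or `"tie"`).
#' @export
score_event_sites <- function(event, model, site_models) {
  S <- model$exons[, "start"]; E <- model$exons[, "end"]
  cmp <- list()                                # site_type, actual, alt
  mech <- event$mechanism
  if (mech %in% c("exon_skip", "multi_exon_skip")) {
    ex <- event$exons
    cmp$acceptor <- c(S[ex[1L]], event$gend)
    cmp$donor <- c(E[ex[length(ex)]], event$gstart)
  } else if (mech == "alt3ss") {
    cmp$acceptor <- c(event$gend - event$shift_nt, event$gend)
  } else if (mech == "alt5ss") {
    cmp$donor <- c(event$gstart - event$shift_nt, event$gstart)
  } else if (mech == "partial_intron_retention") {
    if (event$gstart %in% E) {
      cmp$acceptor <- c(event$gend - event$shift_nt, event$gend)
    } else {
      cmp$donor <- c(event$gstart - event$shift_nt, event$gstart)
    }
  } else if (mech == "alt3ss+alt5ss" && length(event$exons) == 1L) {
    ex <- event$exons
    cmp$donor <- c(E[ex], event$gstart)
    cmp$acceptor <- c(S[ex], event$gend)
  } else {
    stop(sprintf("no site comparison defined for mechanism '%s'", mech))
  }
  rows <- list()
  for (st in names(cmp)) {
    extract <- if (st == "donor") donor_window else acceptor_window
    for (sm in site_models) {
      if (is.null(sm$site_type) || sm$site_type != st) next
      sc <- score_windows(sm, c(extract(model, cmp[[st]][1L]),
                                extract(model, cmp[[st]][2L])))
      rows[[length(rows) + 1L]] <- data.frame(
        event = splice_event_key(list(event)), site_type = st, kind = sm$kind,
        actual_pos = cmp[[st]][1L], alt_pos = cmp[[st]][2L],
        actual_score = sc[1L], alt_score = sc[2L],
        dominant = if (isTRUE(all.equal(sc[1L], sc[2L]))) "tie" else
          if (sc[1L] > sc[2L]) "actual" else "alternative",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "note") <- "scores are comparative only; no absolute threshold applies"
  class(out) <- c("site_comparison", "data.frame")
  out
}
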