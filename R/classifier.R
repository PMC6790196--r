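#' Spliced alignment of a clone transcript to its gene model
#'
#' Builds a chain of maximal matching blocks between a clone transcript and
#' the gene-strand genomic sequence of its gene. Blocks are seeded from
#' unique 15-mer anchors shared by transcript and genome and extended across
#' isolated substitutions (allelic SNPs and clone errors are tolerated; a
#' run of two mismatching bases ends a block). Adjacent blocks in a valid
#' chain are separated by a genomic gap (a splice) and a zero-length
#' transcript gap; junction placement within runs of identical bases is
#' canonicalized by shifting each gap maximally 5'-ward.
#'
#' @param seq clone transcript sequence (character scalar).
#' @param model a [gene_model()].
#' @param k anchor length (default 15).
#' @param min_block minimum block length in nt.
#' @param min_coverage minimum anchored fraction of the transcript below
#'   which the clone is rejected as deriving from a different gene.
#' @return data frame of class `block_chain` with 0-based half-open columns
#'   `gstart`, `gend`, `tstart`, `tend` and per-block `mismatches`; the gene
#'   id and transcript length are attached as attributes.
#' @export
align_transcript <- function(seq, model, k = 15L, min_block = 12L,
                             min_coverage = 0.8) {
  tseq <- toupper(as.character(seq))
  gseq <- model$genomic_seq
  tn <- nchar(tseq); gn <- nchar(gseq)
  if (tn < k) stop("wrong-gene error: transcript shorter than the anchor size")
  gk <- substring(gseq, 1:(gn - k + 1L), k:gn)
  dup <- duplicated(gk) | duplicated(gk, fromLast = TRUE)
  tk <- substring(tseq, 1:(tn - k + 1L), k:tn)
  hit <- match(tk, gk)
  hit[!is.na(hit) & dup[ifelse(is.na(hit), 1L, hit)]] <- NA
  tpos <- which(!is.na(hit))                 # 1-based anchor starts in transcript
  gpos <- hit[tpos]
  if (length(tpos) == 0L) stop("wrong-gene error: no unique anchors found")
  diag <- gpos - tpos
  tv <- strsplit(tseq, "")[[1L]]
  gv <- strsplit(gseq, "")[[1L]]
  blocks <- list()
  for (d in unique(diag)) {
    tp <- tpos[diag == d]
    t0 <- min(tp); t1 <- max(tp) + k - 1L    # 1-based inclusive span
    # extend left
    miss <- 0L
    while (t0 > 1L && t0 + d > 1L) {
      if (tv[t0 - 1L] == gv[t0 - 1L + d]) miss <- 0L else miss <- miss + 1L
      if (miss >= 2L) break
      t0 <- t0 - 1L
    }
    miss <- 0L
    while (t1 < tn && t1 + d < gn) {
      if (tv[t1 + 1L] == gv[t1 + 1L + d]) miss <- 0L else miss <- miss + 1L
      if (miss >= 2L) break
      t1 <- t1 + 1L
    }
    # block edges must be clean: no mismatch within `edge` bases of either
    # end, so a chance match beyond a junction cannot drag the boundary along
    edge <- 8L
    repeat {
      if (t1 < t0) break
      idx <- t0:t1
      mmpos <- idx[tv[idx] != gv[idx + d]]
      lm <- mmpos[mmpos < t0 + edge]
      rm_ <- mmpos[mmpos > t1 - edge]
      if (length(lm) == 0L && length(rm_) == 0L) break
      if (length(lm)) t0 <- max(lm) + 1L
      if (length(rm_)) t1 <- min(rm_) - 1L
    }
    if (t1 >= t0) blocks[[length(blocks) + 1L]] <- c(t0 = t0, t1 = t1, d = d)
  }
  b <- do.call(rbind, blocks)
  b <- b[b[, "t1"] - b[, "t0"] + 1L >= min_block, , drop = FALSE]
  if (nrow(b) == 0L) stop("wrong-gene error: no alignable blocks")
  b <- b[order(b[, "t0"]), , drop = FALSE]
  # drop blocks nested in the previous one; trim transcript overlaps from the
  # upstream block (junction then shifts 5'-ward, the canonical direction)
  keep <- rep(TRUE, nrow(b))
  for (i in seq_len(nrow(b))[-1L]) {
    j <- max(which(keep[seq_len(i - 1L)]))
    if (b[i, "t1"] <= b[j, "t1"]) keep[i] <- FALSE
  }
  b <- b[keep, , drop = FALSE]
  nb <- nrow(b)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      overlap <- b[i, "t1"] - b[i + 1L, "t0"] + 1L
      if (overlap > 0L) b[i, "t1"] <- b[i, "t1"] - overlap
      if (b[i + 1L, "d"] <= b[i, "d"]) {
        stop("unalignable segment: genomic order violated (possible chimera)")
      }
    }
    # rescue unanchored interior segments: a short exon whose substitution
    # destroys every anchor k-mer leaves a transcript gap. Place the whole
    # annotated exon over the gap (flanking blocks may have overreached the
    # junctions by chance matches and are trimmed back to the split that
    # minimizes mismatches), restoring annotated boundaries exactly.
    rescued <- list()
    for (i in seq_len(nb - 1L)) {
      ts <- b[i, "t1"] + 1L; te <- b[i + 1L, "t0"] - 1L
      if (te < ts) next
      seg_len <- te - ts + 1L
      slack_l <- min(8L, b[i, "t1"] - b[i, "t0"])
      slack_r <- min(8L, b[i + 1L, "t1"] - b[i + 1L, "t0"])
      exon_lens <- model$exons[, "end"] - model$exons[, "start"]
      cand <- which(exon_lens >= seg_len &
                      exon_lens <= seg_len + slack_l + slack_r)
      best <- NULL; best_mism <- Inf; best_n <- 0L
      for (e in cand) {
        len <- exon_lens[e]
        for (x in 0:min(slack_l, len - seg_len)) {
          y <- len - seg_len - x
          if (y > slack_r) next
          t0e <- ts - x; t1e <- te + y
          if (t0e < 1L || t1e > tn) next
          mism <- sum(tv[t0e:t1e] !=
                        gv[(model$exons[e, "start"] + 1L):model$exons[e, "end"]])
          if (mism > max(3L, len %/% 5L)) next
          if (mism < best_mism) {
            best_mism <- mism; best_n <- 1L
            best <- list(e = unname(e), x = unname(x), y = unname(y))
          } else if (mism == best_mism) best_n <- best_n + 1L
        }
      }
      if (is.null(best) || best_n > 1L) {
        stop(sprintf(
          "unalignable segment: transcript bases %d-%d match no genomic block",
          ts, te))
      }
      rescued[[length(rescued) + 1L]] <- list(i = i, best = best)
    }
    for (r in rescued) {
      i <- r$i; e <- r$best[["e"]]; x <- r$best[["x"]]; y <- r$best[["y"]]
      b[i, "t1"] <- b[i, "t1"] - x
      b[i + 1L, "t0"] <- b[i + 1L, "t0"] + y
      t0e <- b[i, "t1"] + 1L
      len <- model$exons[e, "end"] - model$exons[e, "start"]
      b <- rbind(b, c(t0 = t0e, t1 = t0e + len - 1L,
                      d = model$exons[e, "start"] + 1L - t0e))
    }
    if (length(rescued)) {
      b <- b[order(b[, "t0"]), , drop = FALSE]
      nb <- nrow(b)
    }
  }
  # absorb short unanchored transcript ends along the flanking diagonal
  # (a substitution close to a clone end leaves too little for an anchor)
  if (b[1L, "t0"] > 1L && b[1L, "t0"] <= 11L && b[1L, "d"] + 1L > 0L) {
    b[1L, "t0"] <- 1L
  }
  if (b[nb, "t1"] < tn && tn - b[nb, "t1"] <= 10L && b[nb, "d"] + tn <= gn) {
    b[nb, "t1"] <- tn
  }
  covered <- sum(b[, "t1"] - b[, "t0"] + 1L)
  if (covered / tn < min_coverage) {
    stop(sprintf("wrong-gene error: only %.0f%% of the transcript aligns to %s",
                 100 * covered / tn, model$gene_id))
  }
  if (b[1L, "t0"] > 1L || b[nb, "t1"] < tn) {
    stop("unalignable segment: transcript ends do not align")
  }
  # canonicalize: shift each junction maximally 5'-ward
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      aEnd <- b[i, "t1"] + b[i, "d"]         # 1-based genomic end of block i
      bStart <- b[i + 1L, "t0"] + b[i + 1L, "d"]
      while (b[i, "t1"] >= b[i, "t0"] && gv[aEnd] == gv[bStart - 1L]) {
        b[i, "t1"] <- b[i, "t1"] - 1L
        b[i + 1L, "t0"] <- b[i + 1L, "t0"] - 1L
        aEnd <- aEnd - 1L; bStart <- bStart - 1L
      }
    }
  }
  mm <- vapply(seq_len(nb), function(i) {
    idx <- b[i, "t0"]:b[i, "t1"]
    sum(tv[idx] != gv[idx + b[i, "d"]])
  }, integer(1))
  out <- data.frame(
    gstart = b[, "t0"] + b[, "d"] - 1L,      # to 0-based half-open
    gend = b[, "t1"] + b[, "d"],
    tstart = b[, "t0"] - 1L,
    tend = b[, "t1"],
    mismatches = mm
  )
  rownames(out) <- NULL
  attr(out, "gene_id") <- model$gene_id
  attr(out, "transcript_length") <- tn
  class(out) <- c("block_chain", "data.frame")
  out
}

# Ambiguity range of a genomic gap [gs, ge) (0-based): how far it can shift
# left/right through runs of identical bases without changing the transcript.
.gap_shift_range <- function(gv, gs, ge) {
  l <- 0L
  while (gs - l > 0L && gv[gs - l] == gv[ge - l]) l <- l + 1L
  r <- 0L
  while (ge + r < length(gv) && gv[gs + r + 1L] == gv[ge + r + 1L]) r <- r + 1L
  c(left = l, right = r)
}

#' Classify splice-junction deviations of an aligned transcript
#'
#' Compares each genomic gap of a block chain against the annotated introns
#' of the gene model, over the gap's whole placement-ambiguity range (the
#' alignment stores gaps maximally 5'-shifted; annotated junctions are
#' matched at any equivalent placement). A gap equal to an annotated intron
#' is constitutive splicing; a gap spanning whole annotated exons with
#' annotated flanks is a (multi-)exon skip; a boundary offset from the
#' annotated acceptor or donor yields an alternative 3'/5' splice site when
#' it deletes exonic sequence, or a partial intron retention when it retains
#' intronic sequence; a gap with both boundaries inside one exon is the
#' paired alternative-3'SS+5'SS class; an annotated intron fully contained
#' in a block is an intron retention, and a block fully inside an intron a
#' cryptic exon. Junction-offset tolerance is zero: any boundary that
#' differs from annotation at every equivalent placement is alternative.
#'
#' @param chain a [align_transcript()] result.
#' @param model the matching [gene_model()].
#' @return list of `splice_event` objects (empty for a constitutive chain),
#'   each with `mechanism`, `exons`, `intron`, `shift_nt`, `delta_len`,
#'   `gstart`, `gend`.
#' @export
classify_events <- function(chain, model) {
  gv <- strsplit(model$genomic_seq, "")[[1L]]
  S <- model$exons[, "start"]; E <- model$exons[, "end"]
  nE <- nrow(model$exons)
  events <- list()
  add <- function(mechanism, exons = integer(0), intron = NA_integer_,
                  shift_nt = NA_integer_, delta_len, gstart, gend) {
    events[[length(events) + 1L]] <<- structure(
      list(mechanism = mechanism, exons = exons, intron = intron,
           shift_nt = shift_nt, delta_len = as.integer(delta_len),
           gstart = as.integer(gstart), gend = as.integer(gend)),
      class = "splice_event")
  }
  # intron retention: annotated intron fully inside one block
  for (i in seq_len(nE - 1L)) {
    inside <- any(chain$gstart <= E[i] & chain$gend >= S[i + 1L])
    if (inside) {
      add("intron_retention", exons = c(i, i + 1L), intron = i,
          delta_len = S[i + 1L] - E[i], gstart = E[i], gend = S[i + 1L])
    }
  }
  # cryptic exon: block fully inside an annotated intron
  for (bi in seq_len(nrow(chain))) {
    gs <- chain$gstart[bi]; ge <- chain$gend[bi]
    intr <- which(E[-nE] <= gs & S[-1L] >= ge)
    if (length(intr)) {
      add("cryptic_exon", intron = intr[1L], delta_len = ge - gs,
          gstart = gs, gend = ge)
    }
  }
  nb <- nrow(chain)
  if (nb < 2L) return(events)
  exon_of <- function(p) {                   # exon whose body contains 0-based p
    w <- which(p >= S & p < E)
    if (length(w)) w[1L] else NA_integer_
  }
  for (i in seq_len(nb - 1L)) {
    gs <- chain$gend[i]; ge <- chain$gstart[i + 1L]      # gap, 0-based half-open
    rng <- .gap_shift_range(gv, gs, ge)
    offs <- seq(-rng["left"], rng["right"])
    # placement matching an annotated donor, and one matching an acceptor
    don_off <- offs[(gs + offs) %in% E]
    acc_off <- offs[(ge + offs) %in% S]
    both <- intersect(don_off, acc_off)
    const <- FALSE
    for (o in both) {
      e <- which(E == gs + o); j <- which(S == ge + o)
      if (length(e) && length(j) && j == e + 1L) { const <- TRUE; break }
    }
    if (const) next
    if (length(both)) {                      # annotated flanks: exon skip
      o <- both[1L]
      e <- which(E == gs + o); j <- which(S == ge + o)
      skipped <- (e + 1L):(j - 1L)
      add(if (length(skipped) > 1L) "multi_exon_skip" else "exon_skip",
          exons = skipped, delta_len = -sum(E[skipped] - S[skipped]),
          gstart = gs + o, gend = ge + o)
      next
    }
    if (length(don_off)) {                   # donor annotated, acceptor shifted
      o <- don_off[1L]
      e <- which(E == gs + o)
      j_next <- which(S >= ge + o)           # first retained downstream exon
      j <- if (length(j_next)) j_next[1L] else nE
      skipped <- if (j > e + 1L) (e + 1L):(j - 1L) else integer(0)
      if (length(skipped)) {
        add(if (length(skipped) > 1L) "multi_exon_skip" else "exon_skip",
            exons = skipped, delta_len = -sum(E[skipped] - S[skipped]),
            gstart = E[e], gend = S[j])
      }
      shift <- (ge + o) - S[j]
      in_exon <- exon_of(ge + o)
      mech <- if (!is.na(in_exon)) "alt3ss" else "partial_intron_retention"
      add(mech, exons = if (!is.na(in_exon)) in_exon else j,
          intron = j - 1L, shift_nt = shift, delta_len = -shift,
          gstart = gs + o, gend = ge + o)
      next
    }
    if (length(acc_off)) {                   # acceptor annotated, donor shifted
      o <- acc_off[1L]
      j <- which(S == ge + o)
      e_prev <- which(E <= gs + o)
      e <- if (length(e_prev)) e_prev[length(e_prev)] else 1L
      skipped <- if (j > e + 1L) (e + 1L):(j - 1L) else integer(0)
      if (length(skipped)) {
        add(if (length(skipped) > 1L) "multi_exon_skip" else "exon_skip",
            exons = skipped, delta_len = -sum(E[skipped] - S[skipped]),
            gstart = E[e], gend = S[j])
      }
      shift <- (gs + o) - E[e]
      in_exon <- exon_of(gs + o - 1L)        # base before gap start
      mech <- if (!is.na(in_exon) && shift < 0L) "alt5ss" else
        if (shift > 0L) "partial_intron_retention" else "alt5ss"
      add(mech, exons = e, intron = e, shift_nt = shift, delta_len = shift,
          gstart = gs + o, gend = ge + o)
      next
    }
    eA <- exon_of(gs - 1L); eB <- exon_of(ge)
    if (!is.na(eA) && !is.na(eB) && eA == eB) {
      # both boundaries internal to one exon: paired alt 3'SS + 5'SS
      add("alt3ss+alt5ss", exons = eA, shift_nt = ge - gs,
          delta_len = -(ge - gs), gstart = gs, gend = ge)
      next
    }
    # unannotated on both sides across exons: report as a paired-site event
    add("alt3ss+alt5ss",
        exons = unique(c(eA, eB)[!is.na(c(eA, eB))]),
        shift_nt = ge - gs, delta_len = NA, gstart = gs, gend = ge)
  }
  events
}

#' @export
print.splice_event <- function(x, ...) {
  cat(sprintf("<splice_event> %s exon(s) %s, delta %s nt [%d,%d)\n",
              x$mechanism, paste(x$exons, collapse = "+"),
              x$delta_len, x$gstart, x$gend))
  invisible(x)
}

#' Canonical key of a splice event (or clone event combination)
#'
#' Events are pooled across clones and animals by mechanism, affected exons
#' and length change; events co-occurring in one clone form one compound key
#' joined by `&`.
#'
#' @param events a `splice_event` or list of them.
#' @return character scalar (`""` for no events).
#' @export
splice_event_key <- function(events) {
  if (inherits(events, "splice_event")) events <- list(events)
  if (length(events) == 0L) return("")
  paste(vapply(events, function(e) {
    sprintf("%s[%s]%+d", e$mechanism, paste(e$exons, collapse = "+"),
            e$delta_len)
  }, character(1)), collapse = "&")
}

#' Predict the protein consequence of an isoform
#'
#' Rebuilds the isoform CDS from the block chain over the gene-model
#' reference (clone sequencing errors are thereby excluded), translates it,
#' and reports: whether the net length change keeps the reading frame; if a
#' stop codon arises upstream of the constitutive stop (premature
#' termination, mapped by genomic position so that frame-preserving
#' isoforms ending at the natural stop are not flagged); which domain-labelled
#' exons survive intact, in frame and upstream of any premature stop; whether
#' the isoform is a candidate soluble form (in frame, no premature stop,
#' transmembrane exon lost); and whether any intact product is expected.
#'
#' @param events events from [classify_events()].
#' @param model the [gene_model()].
#' @param chain the [align_transcript()] chain the events came from.
#' @return list of class `isoform_consequence`.
#' @export
predict_consequence <- function(events, model, chain) {
  delta <- sum(vapply(events, function(e) {
    if (is.na(e$delta_len)) 0L else e$delta_len
  }, integer(1)))
  in_frame <- delta %% 3L == 0L
  iso <- paste(substring(model$genomic_seq, chain$gstart + 1L, chain$gend),
               collapse = "")
  # translation start in isoform coordinates
  hit <- which(chain$gstart <= model$cds_start & chain$gend > model$cds_start)
  if (length(hit) == 0L) {
    return(structure(list(in_frame = in_frame, premature_stop = TRUE,
                          domains_retained = character(0), soluble = FALSE,
                          product_expected = FALSE, delta_len = delta,
                          first_stop_codon_index = NA_integer_),
                     class = "isoform_consequence"))
  }
  iso_off <- sum(chain$tend[seq_len(hit - 1L)] - chain$tstart[seq_len(hit - 1L)]) +
    (model$cds_start - chain$gstart[hit])
  pr <- translate_and_scan(iso, iso_off)
  g_stop_const <- transcript_to_genomic(
    model, cds_offset_in_mrna(model) + 3L * (model$cds_codon_count - 1L))
  premature <- FALSE
  g_stop_iso <- NA_integer_
  if (!is.na(pr$first_stop_codon_index)) {
    t_stop <- iso_off + 3L * (pr$first_stop_codon_index - 1L)   # 0-based in iso
    bi <- which(chain$tstart <= t_stop & chain$tend > t_stop)
    g_stop_iso <- chain$gstart[bi] + (t_stop - chain$tstart[bi])
    premature <- g_stop_iso != g_stop_const
  }
  S <- model$exons[, "start"]; E <- model$exons[, "end"]
  # an exon is intact unless an excising event touches it (retention-type
  # events add sequence without removing exonic bases); coverage cannot be
  # read off the blocks directly because junction canonicalization shifts
  # equivalent bases across gaps
  excising <- c("exon_skip", "multi_exon_skip", "alt3ss", "alt5ss",
                "alt3ss+alt5ss")
  covered <- vapply(seq_len(nrow(model$exons)), function(e) {
    !any(vapply(events, function(ev) {
      ev$mechanism %in% excising && e %in% ev$exons
    }, logical(1)))
  }, logical(1))
  upstream_delta <- vapply(seq_len(nrow(model$exons)), function(e) {
    sum(vapply(events, function(ev) {
      if (!is.na(ev$delta_len) && ev$gend <= S[e]) ev$delta_len else 0L
    }, integer(1)))
  }, integer(1))
  retained <- covered & upstream_delta %% 3L == 0L
  if (premature && !is.na(g_stop_iso)) retained <- retained & E <= g_stop_iso + 3L
  domains <- unique(model$domain_labels[retained])
  soluble <- in_frame && !premature && !("TM" %in% model$domain_labels[retained])
  structure(list(in_frame = in_frame, premature_stop = premature,
                 domains_retained = domains, soluble = soluble,
                 product_expected = !premature, delta_len = delta,
                 first_stop_codon_index = pr$first_stop_codon_index),
            class = "isoform_consequence")
}

#' @export
print.isoform_consequence <- function(x, ...) {
  cat(sprintf(
    "<isoform_consequence> %s, %s; domains: %s%s%s\n",
    if (x$in_frame) "in frame" else "frameshift",
    if (x$premature_stop) "premature stop" else "no premature stop",
    paste(x$domains_retained, collapse = ","),
    if (x$soluble) "; soluble candidate" else "",
    if (x$product_expected) "" else "; no product expected"))
  invisible(x)
}

#' Align and classify a whole clone library
#'
#' Runs [align_transcript()] and [classify_events()] for every clone against
#' its assigned gene model. Clones whose transcripts cannot be anchored to
#' their gene are reported (`wrong_gene`/`unalignable`), not classified.
#'
#' @param clones a [simulate_clone_library()]-style data frame (columns
#'   `clone_id`, `gene`, `seq`; a `gene` assignment is required).
#' @param models named list of [gene_model()] objects.
#' @return data frame with `clone_id`, `gene`, `status` (`ok`, `wrong_gene`,
#'   `unalignable`), `event_key` (compound key, `""` if constitutive) and
#'   `n_events`; per-clone event lists are attached as attribute `events`.
#' @export
classify_transcripts <- function(clones, models) {
  n <- nrow(clones)
  status <- character(n); key <- character(n); nev <- integer(n)
  evlist <- vector("list", n)
  for (i in seq_len(n)) {
    m <- models[[clones$gene[i]]]
    res <- tryCatch({
      ch <- align_transcript(clones$seq[i], m)
      ev <- classify_events(ch, m)
      list(status = "ok", key = splice_event_key(ev), n = length(ev), ev = ev)
    }, error = function(e) {
      st <- if (grepl("wrong-gene", conditionMessage(e))) "wrong_gene" else "unalignable"
      list(status = st, key = NA_character_, n = NA_integer_, ev = NULL)
    })
    status[i] <- res$status; key[i] <- res$key; nev[i] <- res$n
    evlist[[i]] <- res$ev
  }
  out <- data.frame(clone_id = clones$clone_id, gene = clones$gene,
                    status = status, event_key = key, n_events = nev,
                    stringsAsFactors = FALSE)
  attr(out, "events") <- stats::setNames(evlist, clones$clone_id)
  out
}

#' Tally classified splice events across a clone set
#'
#' Pools identical events (same compound key) across clones and animals,
#' breaks counts down per gene, and splits the table into categorized
#' (count >= `min_count`) and uncategorized events, following the practice
#' of categorizing only events observed more than three times.
#'
#' @param classified a [classify_transcripts()] result (only `status ==
#'   "ok"` clones with at least one event are tallied).
#' @param min_count categorization threshold (default 4).
#' @return data frame with `event_key`, one count column per gene, `count`
#'   (total) and `categorized`, ordered by decreasing count.
#' @export
tally_events <- function(classified, min_count = 4L) {
  ok <- classified$status == "ok" & !is.na(classified$event_key) &
    classified$event_key != ""
  sub <- classified[ok, , drop = FALSE]
  genes <- sort(unique(classified$gene))
  if (nrow(sub) == 0L) {
    out <- data.frame(event_key = character(0))
    for (g in genes) out[[g]] <- integer(0)
    out$count <- integer(0); out$categorized <- logical(0)
    return(out)
  }
  tab <- table(sub$event_key, factor(sub$gene, levels = genes))
  out <- data.frame(event_key = rownames(tab), stringsAsFactors = FALSE)
  for (g in genes) out[[g]] <- as.integer(tab[, g])
  out$count <- as.integer(rowSums(tab))
  out$categorized <- out$count >= min_count
  out <- out[order(-out$count, out$event_key), , drop = FALSE]
  rownames(out) <- NULL
  out
}
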