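test_that("constitutive transcripts align one block per exon with intron gaps", {
  sim <- small_sim()
  m <- sim$models[[1L]]
  ch <- align_transcript(constitutive_mrna(m), m)
  expect_identical(nrow(ch), nrow(m$exons))
  expect_length(classify_events(ch, m), 0L)
  # transcript gaps between adjacent blocks are zero by construction
  expect_true(all(ch$tstart[-1L] == ch$tend[-nrow(ch)]))
})

test_that("exon skips are recovered with exact gap arithmetic", {
  sim <- small_sim()
  m <- sim$models[[1L]]
  t4 <- splice_out(m, setdiff(1:9, 4L))
  ch <- align_transcript(t4, m)
  ev <- classify_events(ch, m)
  expect_length(ev, 1L)
  expect_identical(ev[[1L]]$mechanism, "exon_skip")
  expect_identical(ev[[1L]]$exons, 4L)
  # the gap spans intron3 + exon4 + intron4 exactly
  expect_identical(ev[[1L]]$gstart, unname(m$exons[3L, "end"]))
  expect_identical(ev[[1L]]$gend, unname(m$exons[5L, "start"]))
  expect_identical(ev[[1L]]$delta_len,
                   unname(-(m$exons[4L, "end"] - m$exons[4L, "start"])))
  # multi-exon skip of exons 3 to 5
  ev35 <- classify_events(align_transcript(splice_out(m, setdiff(1:9, 3:5)), m), m)
  expect_length(ev35, 1L)
  expect_identical(ev35[[1L]]$mechanism, "multi_exon_skip")
  expect_identical(ev35[[1L]]$exons, 3:5)
})

test_that("an exon-internal deletion yields the paired alt-3'SS+5'SS class", {
  sim <- small_sim()
  cfg <- sim$config
  for (g in seq_along(sim$models)) {
    m <- sim$models[[g]]
    td <- splicekin:::.event_transcript(
      m, m$genomic_seq, list(mechanism = "alt_pair_deletion", exon = 2L), cfg)
    ch <- align_transcript(td$seq, m)
    # exon 2 splits into two blocks with a 112-nt genomic, 0-nt transcript gap
    gaps <- ch$gstart[-1L] - ch$gend[-nrow(ch)]
    expect_identical(sum(gaps == 112L), 1L)
    expect_identical(nrow(ch), nrow(m$exons) + 1L)
    ev <- classify_events(ch, m)
    expect_length(ev, 1L)
    expect_identical(ev[[1L]]$mechanism, "alt3ss+alt5ss")
    expect_identical(ev[[1L]]$exons, 2L)
    expect_identical(ev[[1L]]$delta_len, -112L)
  }
})

test_that("intron retention and cryptic exons are detected", {
  sim <- small_sim()
  m <- sim$models[[1L]]
  gv <- m$genomic_seq
  # retain intron 3: splice exon3..exon4 as one block
  tIR <- paste0(splice_out(m, 1:2),
                substr(gv, m$exons[3L, "start"] + 1L, m$exons[4L, "end"]),
                splice_out(m, 5:9))
  ev <- classify_events(align_transcript(tIR, m), m)
  ir <- Filter(function(e) e$mechanism == "intron_retention", ev)
  expect_length(ir, 1L)
  expect_identical(ir[[1L]]$intron, 3L)
  expect_identical(ir[[1L]]$delta_len,
                   unname(m$exons[4L, "start"] - m$exons[3L, "end"]))
})

test_that("protein consequences follow the frame rule", {
  sim <- small_sim()
  cfg <- sim$config
  m <- sim$models[[1L]]
  # exon-4 (TM) skip: in frame, soluble candidate
  ch4 <- align_transcript(splice_out(m, setdiff(1:9, 4L)), m)
  cq4 <- predict_consequence(classify_events(ch4, m), m, ch4)
  expect_true(cq4$in_frame)
  expect_false(cq4$premature_stop)
  expect_true(cq4$soluble)
  expect_true(cq4$product_expected)
  expect_false("TM" %in% cq4$domains_retained)
  # 112-nt deletion: frameshift (112 %% 3 == 1), premature stop, no product
  td <- splicekin:::.event_transcript(
    m, m$genomic_seq, list(mechanism = "alt_pair_deletion", exon = 2L), cfg)
  chd <- align_transcript(td$seq, m)
  cqd <- predict_consequence(classify_events(chd, m), m, chd)
  expect_false(cqd$in_frame)
  expect_true(cqd$premature_stop)
  expect_false(cqd$product_expected)
  # constitutive: all annotated domains retained
  ch0 <- align_transcript(constitutive_mrna(m), m)
  cq0 <- predict_consequence(list(), m, ch0)
  expect_true(cq0$in_frame)
  expect_false(cq0$premature_stop)
  expect_setequal(cq0$domains_retained, unique(m$domain_labels))
  # frame arithmetic cross-checked against direct translation for the
  # in-frame heptad skip (exon 6)
  ch6 <- align_transcript(splice_out(m, setdiff(1:9, 6L)), m)
  cq6 <- predict_consequence(classify_events(ch6, m), m, ch6)
  expect_true(cq6$in_frame)
  expect_false(cq6$premature_stop)
  pr <- translate_and_scan(splice_out(m, setdiff(1:9, 6L)), cds_offset_in_mrna(m))
  expect_identical(pr$first_stop_codon_index,
                   unname(m$cds_codon_count -
                            (m$exons[6L, "end"] - m$exons[6L, "start"]) %/% 3L))
})

test_that("classification round-trips every planted event at error rate 0", {
  cfg <- cohort_config(seed = 17L, clone_error_rate = 0,
                       generations = 3L, n_families = 1L, clone_depth = 16L)
  sim <- simulate_family(cfg)
  clones <- simulate_clone_library(sim)
  expect_gte(nrow(clones), 500L)
  res <- classify_transcripts(clones, sim$models)
  expect_true(all(res$status == "ok"))
  expect_identical(res$event_key, clones$event_true)
})

test_that("clones with substitution errors still classify cleanly", {
  sim <- small_sim()
  m <- sim$models[[1L]]
  t4 <- splice_out(m, setdiff(1:9, 4L))
  set.seed(99)
  junctions <- cumsum((m$exons[, "end"] - m$exons[, "start"])[setdiff(1:9, 4L)])
  interior <- setdiff(seq_len(nchar(t4)),
                      unlist(lapply(c(0L, junctions), function(j) (j - 9L):(j + 10L))))
  for (rep in 1:20) {
    sv <- strsplit(t4, "")[[1L]]
    pos <- sample(interior, 3L)
    for (p in pos) sv[p] <- sample(setdiff(c("A", "C", "G", "T"), sv[p]), 1L)
    ev <- classify_events(align_transcript(paste(sv, collapse = ""), m), m)
    expect_identical(splice_event_key(ev), "exon_skip[4]-117")
  }
})

test_that("transcripts from the wrong gene are rejected, not classified", {
  sim <- small_sim()
  expect_error(align_transcript(constitutive_mrna(sim$models[[2L]]),
                                sim$models[[1L]]),
               "wrong-gene")
})

test_that("event tallies pool by compound key and respect min_count", {
  cls <- data.frame(
    clone_id = sprintf("c%d", 1:10),
    gene = c(rep("gA", 6), rep("gB", 4)),
    status = "ok",
    event_key = c(rep("exon_skip[4]-117", 4), "", "alt3ss+alt5ss[2]-112",
                  rep("exon_skip[4]-117", 3), ""),
    n_events = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 0))
  tal <- tally_events(cls, min_count = 4L)
  expect_identical(tal$count[tal$event_key == "exon_skip[4]-117"], 7L)
  expect_identical(tal$gA[tal$event_key == "exon_skip[4]-117"], 4L)
  expect_identical(tal$gB[tal$event_key == "exon_skip[4]-117"], 3L)
  expect_true(tal$categorized[tal$event_key == "exon_skip[4]-117"])
  # observed three times or fewer stays uncategorized; four categorizes
  expect_false(tal$categorized[tal$event_key == "alt3ss+alt5ss[2]-112"])
  # monotonicity: raising min_count never adds categorized events
  for (mc in c(1L, 2L, 4L, 8L)) {
    t_lo <- tally_events(cls, min_count = mc)
    t_hi <- tally_events(cls, min_count = mc + 1L)
    expect_true(all(t_lo$event_key[t_hi$categorized] %in%
                      t_lo$event_key[t_lo$categorized]))
  }
  expect_identical(nrow(tally_events(cls[0, ], 4L)), 0L)
})
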