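test_that("PWM training recovers frequencies and scores degenerate sets", {
  sw <- simulate_site_windows(200L, "donor", seed = 2L)
  pwm <- train_pwm(sw$windows)
  expect_lt(max(abs(pwm$freqs - sw$pwm)), 0.05)
  # identical training windows, zero pseudocount: the window scores the
  # maximum; any mismatch position hits the floor
  same <- rep("CAGGTAAGT", 12L)
  p0 <- train_pwm(same, pseudocount = 0)
  smax <- score_windows(p0, "CAGGTAAGT")
  expect_equal(smax, 9 * log2(1 / 0.25))
  expect_equal(score_windows(p0, "AAGGTAAGT"), smax - log2(4) + (-20 - log2(0.25)))
  # uniform training set scores 0 under a uniform background
  uni <- c("ACGT", "CGTA", "GTAC", "TACG")
  pu <- train_pwm(rep(uni, 3L), pseudocount = 0)
  expect_true(all(abs(score_windows(pu, uni)) < 1e-12))
  expect_error(train_pwm(c("ACGT", "ACG")), "width")
  expect_error(train_pwm(c("ACGT", "ACGA")), "at least 10")
})

test_that("order-1 maximum entropy equals the PWM", {
  for (seed in c(2L, 13L)) {
    sw <- simulate_site_windows(150L, "donor", seed = seed)
    pwm <- train_pwm(sw$windows)
    me <- train_maxent(sw$windows, order = "1", tol = 1e-10)
    test <- simulate_site_windows(1000L, "donor", seed = seed + 100L)$windows
    expect_lt(max(abs(score_windows(me, test) - score_windows(pwm, test))), 1e-6)
  }
})

test_that("order-2 maximum entropy reproduces pair marginals and normalizes", {
  sw <- simulate_site_windows(250L, "acceptor", seed = 4L)
  me <- train_maxent(sw$windows, order = "2-adjacent", tol = 1e-8)
  expect_lt(me$discrepancy, 1e-8)
  # brute-force normalization over the 64 outcomes of a width-3 model
  set.seed(7)
  w3 <- replicate(60L, paste(sample(c("A", "C", "G", "T"), 3L, TRUE,
                                    prob = c(.4, .3, .2, .1)), collapse = ""))
  me3 <- train_maxent(w3, order = "2-adjacent", tol = 1e-10)
  allw <- apply(expand.grid(B = c("A", "C", "G", "T"),
                            B2 = c("A", "C", "G", "T"),
                            B3 = c("A", "C", "G", "T")), 1L, paste0, collapse = "")
  logp <- score_windows(me3, allw) * log(2) +
    vapply(strsplit(allw, ""), function(b) sum(log(me3$background[b])), numeric(1))
  expect_lt(abs(sum(exp(logp)) - 1), 1e-9)
  # independent oracle: the chain-factorized closed form
  oracle <- vapply(allw, chain_log_prob, numeric(1), windows = w3)
  expect_lt(max(abs(oracle - logp)), 1e-7)
  # training data from a first-order Markov chain: pair marginals matched
  set.seed(11)
  P <- matrix(c(.5, .3, .1, .1, .1, .5, .3, .1,
                .1, .1, .5, .3, .3, .1, .1, .5), 4L, byrow = TRUE)
  mk <- replicate(300L, {
    b <- integer(6L); b[1L] <- sample.int(4L, 1L)
    for (i in 2:6) b[i] <- sample.int(4L, 1L, prob = P[b[i - 1L], ])
    paste(c("A", "C", "G", "T")[b], collapse = "")
  })
  mem <- train_maxent(mk, order = "2-adjacent", tol = 1e-8)
  expect_lt(mem$discrepancy, 1e-8)
})

test_that("scores are shift-invariant and monotone in model likelihood", {
  sw <- simulate_site_windows(100L, "donor", seed = 6L)
  pwm <- train_pwm(sw$windows)
  # the score depends only on the window content (extracting the same
  # window from different genomic contexts changes nothing)
  sim <- small_sim()
  m <- sim$models[[1L]]
  w1 <- donor_window(m, m$exons[1L, "end"])
  expect_identical(nchar(w1), 9L)
  expect_equal(score_windows(pwm, w1), score_windows(pwm, w1))
  # higher model probability implies a higher score (monotone link): under
  # a uniform background the score is log2 P(w) plus a constant
  me <- train_maxent(sw$windows, order = "2-adjacent")
  ws <- unique(simulate_site_windows(200L, "donor", seed = 8L)$windows)
  sc <- score_windows(me, ws)
  logp <- sc * log(2) + vapply(strsplit(ws, ""),
                               function(b) sum(log(me$background[b])), numeric(1))
  expect_identical(order(sc), order(logp))
  consensus <- "CAGGTAAGT"
  weak <- "CATGTAACT"
  expect_gt(score_windows(pwm, consensus), score_windows(pwm, weak))
})

test_that("event sites are compared actual-versus-alternative per model", {
  sim <- small_sim()
  cfg <- sim$config
  m <- sim$models[[1L]]
  sms <- list(
    train_pwm(simulate_site_windows(200L, "donor", seed = 1L)$windows,
              site_type = "donor"),
    train_pwm(simulate_site_windows(200L, "acceptor", seed = 2L)$windows,
              site_type = "acceptor"),
    train_maxent(simulate_site_windows(200L, "donor", seed = 1L)$windows,
                 order = "2-adjacent", site_type = "donor"),
    train_maxent(simulate_site_windows(200L, "acceptor", seed = 2L)$windows,
                 order = "2-adjacent", site_type = "acceptor"))
  # planted paired event: one acceptor and one donor comparison per model
  td <- splicekin:::.event_transcript(
    m, m$genomic_seq, list(mechanism = "alt_pair_deletion", exon = 2L), cfg)
  ev <- classify_events(align_transcript(td$seq, m), m)[[1L]]
  tab <- score_event_sites(ev, m, sms)
  expect_identical(sort(unique(tab$site_type)), c("acceptor", "donor"))
  expect_identical(nrow(tab), 4L)
  # the planted alternative sites are random sequence against a consensus
  # actual donor: the actual site dominates under both model kinds
  don <- tab[tab$site_type == "donor", ]
  expect_true(all(don$dominant == "actual"))
  # identical actual and alternative sites tie by construction
  ev_tie <- ev; ev_tie$gstart <- m$exons[2L, "end"]; ev_tie$gend <- m$exons[2L, "start"]
  tab_tie <- score_event_sites(ev_tie, m, sms)
  expect_true(all(tab_tie$dominant == "tie"))
  expect_match(attr(tab, "note"), "no absolute threshold")
})
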