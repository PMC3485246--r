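test_that("scan_ball returns exactly the windows within 2d", {
  s <- paste0("TTTT", "ACGTACGT", "TTTTT")
  hit <- scan_ball(s, "ACGTACGT", 1)
  expect_true(4 %in% hit$position)
  expect_equal(hit$distance[hit$position == 4], 0L)

  # naive re-scan oracle on random input
  set.seed(401)
  for (rep in 1:10) {
    s <- random_seq(60)
    x <- random_word(8)
    d <- 2
    windows <- substring(s, 1:(60 - 8 + 1), 8:60)
    dist <- oracle_hamming(rep(x, length(windows)), windows)
    keep <- which(dist <= 2 * d)
    got <- scan_ball(s, x, d)
    expect_equal(got$position, keep - 1L)
    expect_equal(got$distance, as.integer(dist[keep]))
    expect_equal(got$lmer, windows[keep])
  }

  # all windows beyond 2d
  far <- scan_ball(strrep("A", 30), strrep("T", 8), 1)
  expect_equal(nrow(far), 0)
  expect_error(scan_ball("ACG", "ACGTACGT", 1), "shorter")
})

test_that("reference selection minimizes the summed candidate counts", {
  x <- strrep("ACGT", 2)                       # l = 8, d = 1
  s_near <- paste0(strrep("T", 10), x, strrep("T", 10))   # exact copy: huge count
  s_far  <- paste0(strrep("T", 10), "AGGGACGA", strrep("T", 10))  # distance 2d
  seqs <- c(random_seq(28), s_near, s_far)
  seqs[1] <- paste0(x, strrep("T", 20))        # s1 holds x itself
  r <- select_reference(seqs, x, 1)
  expect_equal(r, 3L)

  # t = 2: only possible choice
  expect_equal(select_reference(seqs[1:2], x, 1), 2L)

  # identical sequences tie: lowest index wins
  expect_equal(select_reference(c(seqs[1], s_far, s_far), x, 1), 2L)
})

test_that("the filtering rules match their definitions and are sound", {
  x  <- paste0(strrep("A", 7), strrep("G", 8))
  xp <- paste0(strrep("A", 7), strrep("C", 8))
  z1 <- paste0(strrep("T", 4), strrep("A", 3), strrep("G", 8))
  z2 <- paste0(strrep("A", 7), strrep("T", 8))

  expect_false(rule1(z1, x, xp, 4))   # distance 12 to x' exceeds 2d
  expect_true(rule1(z2, x, xp, 4))    # all three distances are 8 <= 2d
  expect_true(rule1(x, x, xp, 4))
  expect_true(rule2(z1, x, xp, 4))    # statistic 4 + 0 <= d
  expect_false(rule2(z2, x, xp, 4))   # statistic 0 + 8 > d
  expect_true(rule2(xp, x, xp, 4))    # (0, 0) is always admissible at h <= 2d

  # soundness: anything discarded is > d from every shared candidate
  set.seed(402)
  l <- 8; d <- 2
  for (rep in 1:150) {
    x <- random_word(l)
    xp <- mutate_word(x, sample(0:(2 * d), 1))
    z <- random_word(l)
    cand <- enumerate_candidates(x, xp, d)
    if (length(cand) == 0) next
    discarded <- !rule1(z, x, xp, d) || !rule2(z, x, xp, d)
    if (discarded) {
      expect_gt(min(hamming_dist(z, cand)), d)
    }
  }
})

test_that("pair search with d = 0 finds exact common l-mers", {
  core <- "ACGTACGTAT"
  seqs <- c(paste0("GG", core, "TT"), paste0(core, "CCCC"),
            paste0("TTTT", core))
  fit <- pair_search(seqs, 10, 0, score = FALSE)
  expect_true(core %in% fit$motifs$motif)
  expect_equal(fit$motifs$motif, brute_force_search(seqs, 10, 0))
})

test_that("pair search equals brute force on random small instances", {
  set.seed(403)
  for (rep in 1:12) {
    l <- sample(4:8, 1)
    d <- sample(0:2, 1)
    if (d >= l) d <- l - 1
    t <- sample(2:5, 1)
    n <- sample((l + 2):50, 1)
    seqs <- vapply(seq_len(t), function(i) random_seq(n), character(1))
    fit <- pair_search(seqs, l, d, score = FALSE)
    expect_identical(fit$motifs$motif, brute_force_search(seqs, l, d))
  }
})

test_that("every accepted motif verifies against all sequences", {
  set.seed(404)
  ds <- simulate_planted(l = 7, d = 1, t = 6, n = 60, seed = 99)
  fit <- pair_search(ds$sequences, 7, 1, score = FALSE)
  expect_gt(nrow(fit$motifs), 0)
  for (m in fit$motifs$motif) {
    for (s in ds$sequences$seq) {
      windows <- substring(s, 1:(nchar(s) - 6), 7:nchar(s))
      expect_lte(min(hamming_dist(rep(m, length(windows)), windows)), 1)
    }
  }
})

test_that("the motif set is invariant under reordering of sequences 2..t", {
  set.seed(405)
  ds <- simulate_planted(l = 8, d = 2, t = 5, n = 50, seed = 7)
  seqs <- ds$sequences
  fit1 <- pair_search(seqs, 8, 2, score = FALSE)
  perm <- seqs[c(1, 4, 2, 5, 3), ]
  fit2 <- pair_search(perm, 8, 2, score = FALSE)
  expect_identical(fit1$motifs$motif, fit2$motifs$motif)
})

test_that("planted datasets are recovered by construction", {
  ds <- simulate_planted(l = 11, d = 2, t = 20, n = 100, seed = 5)
  fit <- pair_search(ds$sequences, 11, 2, score = FALSE)
  expect_true(ds$motif %in% fit$motifs$motif)
})

test_that("degenerate and invalid inputs are rejected or handled", {
  expect_error(pair_search("ACGT", 4, 1), "two sequences")
  expect_error(pair_search(c("ACGT", "AC"), 4, 1), "shorter than")
  expect_error(pair_search(c("ACGTA", "ACGTA"), 4, 4), "0 <= d < l")
  expect_error(brute_force_search(c(strrep("A", 20), strrep("A", 20)),
                                  13, 1), "l <= 12")
  # loose radius: with d = l - 1 some motif always exists
  expect_gt(length(brute_force_search(c("ACGTACG", "TTTTTTT"), 4, 3)), 0)
  # non-ACGT windows are skipped with a warning, not fatal
  expect_warning(
    fit <- pair_search(c("ACGTNACGTACGT", "ACGTAACGTACGT"), 4, 0),
    "skipped"
  )
})
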