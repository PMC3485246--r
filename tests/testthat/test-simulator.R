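test_that("planted datasets have the declared geometry and ground truth", {
  ds <- simulate_planted(l = 15, d = 4, t = 20, n = 600, seed = 1)
  expect_equal(nrow(ds$sequences), 20)
  expect_true(all(nchar(ds$sequences$seq) == 600))
  expect_equal(nchar(ds$motif), 15)
  expect_equal(nrow(ds$manifest), 20)

  # each instance sits verbatim at its recorded position
  for (i in seq_len(20)) {
    s <- ds$sequences$seq[i]
    at <- ds$manifest$position[i]
    expect_identical(substr(s, at + 1, at + 15), ds$manifest$instance[i])
  }
  # exactly-d mode: every instance at distance exactly d
  expect_true(all(hamming_dist(ds$manifest$instance, ds$motif) == 4))
  expect_equal(ds$manifest$mutations, rep(4L, 20))
  expect_true(all(ds$manifest$position >= 0 &
                  ds$manifest$position <= 600 - 15))
})

test_that("at_most_d mode draws mutation counts from 0..d", {
  ds <- simulate_planted(l = 10, d = 3, t = 200, n = 30, seed = 8,
                         mutation_mode = "at_most_d")
  dist <- hamming_dist(ds$manifest$instance, ds$motif)
  expect_true(all(dist <= 3))
  expect_equal(as.integer(dist), ds$manifest$mutations)
  expect_setequal(unique(ds$manifest$mutations), 0:3)
})

test_that("identical seeds reproduce identical datasets, different differ", {
  a <- simulate_planted(l = 9, d = 2, t = 4, n = 50, seed = 123)
  b <- simulate_planted(l = 9, d = 2, t = 4, n = 50, seed = 123)
  c <- simulate_planted(l = 9, d = 2, t = 4, n = 50, seed = 124)
  expect_identical(a$sequences, b$sequences)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$sequences, c$sequences))

  # byte-identical FASTA round trip
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  m1 <- tempfile(); m2 <- tempfile()
  write_planted(a, f1, m1)
  write_planted(b, f2, m2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(m1), readLines(m2))
  expect_equal(read_manifest(m1), a$manifest)
})

test_that("simulation leaves the caller's RNG state untouched", {
  set.seed(42)
  before <- .Random.seed
  invisible(simulate_planted(l = 8, d = 1, t = 3, n = 20, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("d = 0 plants the motif verbatim and search recovers it", {
  ds <- simulate_planted(l = 8, d = 0, t = 5, n = 40, seed = 77)
  expect_true(all(ds$manifest$instance == ds$motif))
  expect_true(all(vapply(ds$sequences$seq, grepl, logical(1),
                         pattern = ds$motif, fixed = TRUE)))
  fit <- pair_search(ds$sequences, 8, 0, score = FALSE)
  expect_true(ds$motif %in% fit$motifs$motif)
})

test_that("inadmissible geometry is rejected", {
  expect_error(simulate_planted(l = 10, d = 2, t = 3, n = 8, seed = 1))
  expect_error(simulate_planted(l = 5, d = 5, t = 3, n = 20, seed = 1),
               "0 <= d < l")
})

test_that("tidy and glance summarize a planted dataset", {
  ds <- simulate_planted(l = 8, d = 1, t = 3, n = 30, seed = 3)
  td <- tidy(ds)
  expect_true(all(c("id", "position", "instance", "mutations",
                    "motif") %in% names(td)))
  gl <- glance(ds)
  expect_equal(gl$t, 3L)
  expect_equal(gl$motif, ds$motif)
})
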