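# Independent oracles and generators, deliberately built on plain
# character comparison rather than the package's encoded paths.

BASES <- c("A", "C", "G", "T")

random_word <- function(l) paste(sample(BASES, l, replace = TRUE),
                                 collapse = "")

random_seq <- random_word

# flip exactly h positions of w to a different base
mutate_word <- function(w, h) {
  chars <- strsplit(w, "")[[1]]
  if (h > 0) {
    pos <- sample.int(length(chars), h)
    for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

# naive positional Hamming distance
oracle_hamming <- function(a, b) {
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

# all 4^l words (l small), as a character matrix (rows = words) plus strings
all_words_mat <- function(l) {
  g <- do.call(expand.grid,
               c(rep(list(BASES), l), stringsAsFactors = FALSE))
  as.matrix(g[, rev(seq_len(l)), drop = FALSE])  # column 1 = first base
}

words_from_mat <- function(mat) {
  apply(mat, 1, paste, collapse = "")
}

# distances of every row of mat to word w, vectorized
mat_dist <- function(mat, w) {
  chars <- strsplit(w, "")[[1]]
  rowSums(mat != matrix(chars, nrow(mat), length(chars), byrow = TRUE))
}

# exhaustive ball-intersection oracle over all 4^l words
oracle_intersection <- function(x, x_prime, d) {
  l <- nchar(x)
  mat <- all_words_mat(l)
  keep <- mat_dist(mat, x) <= d & mat_dist(mat, x_prime) <= d
  sort(words_from_mat(mat[keep, , drop = FALSE]))
}
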