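#' Simulate a planted (l,d) motif dataset
#'
#' Generates `t` i.i.d. uniform background sequences of length `n`, draws a
#' uniform random motif of length `l`, and implants one mutated occurrence
#' per sequence at a uniformly chosen position (overwriting the background,
#' so lengths stay `n`). Under `mutation_mode = "exactly_d"` — the standard
#' fixed-mutation benchmark model — every occurrence differs from the motif
#' in exactly `d` positions; under `"at_most_d"` the mutation count is drawn
#' uniformly from `0..d`. Mutated positions are a uniform subset and each
#' mutated base is replaced by a uniformly chosen different base.
#'
#' All randomness flows from `seed` through one stream in a fixed order
#' (motif bases first, then per sequence: background, mutation count,
#' mutated positions, replacement bases, implant position), so identical
#' seeds reproduce identical datasets byte for byte. The caller's RNG
#' state is left untouched.
#'
#' @param l Motif length in bases.
#' @param d Maximum mutations per occurrence, `0 <= d < l`.
#' @param t Number of sequences (default 20, the conventional benchmark
#'   scale).
#' @param n Sequence length (default 600, likewise).
#' @param seed Integer seed; required, to make ground truth reproducible.
#' @param mutation_mode `"exactly_d"` (default) or `"at_most_d"`.
#' @return An object of class `planted_dataset`: list with `sequences`
#'   (tibble `id`, `seq`), `motif` (the planted word), `manifest` (tibble
#'   `id`, `position` 0-based, `instance`, `mutations`), `params`, `seed`.
#' @examples
#' ds <- simulate_planted(l = 11, d = 2, t = 5, n = 80, seed = 42)
#' ds$motif
#' ds$manifest
#' @export
simulate_planted <- function(l, d, t = 20, n = 600, seed,
                             mutation_mode = c("exactly_d", "at_most_d")) {
  check_params(l, d)
  mutation_mode <- match.arg(mutation_mode)
  stopifnot(length(t) == 1, t >= 1, length(n) == 1, n >= l,
            length(seed) == 1, seed == as.integer(seed))
  bases <- c("A", "C", "G", "T")
  withr::with_seed(as.integer(seed), {
    motif_chars <- sample(bases, l, replace = TRUE)
    motif <- paste(motif_chars, collapse = "")
    rows <- vector("list", t)
    seqs <- character(t)
    for (i in seq_len(t)) {
      bg <- sample(bases, n, replace = TRUE)
      m <- if (mutation_mode == "exactly_d") d else sample(0:d, 1)
      inst <- motif_chars
      if (m > 0) {
        pos <- sample.int(l, m)
        for (p in pos) {
          inst[p] <- sample(setdiff(bases, inst[p]), 1)
        }
      }
      at <- sample.int(n - l + 1, 1) - 1L  # 0-based implant offset
      bg[(at + 1):(at + l)] <- inst
      seqs[i] <- paste(bg, collapse = "")
      rows[[i]] <- tibble::tibble(
        id = sprintf("seq%d", i), position = at,
        instance = paste(inst, collapse = ""), mutations = as.integer(m)
      )
    }
    structure(
      list(
        sequences = tibble::tibble(id = sprintf("seq%d", seq_len(t)),
                                   seq = seqs),
        motif = motif,
        manifest = dplyr::bind_rows(rows),
        params = list(l = as.integer(l), d = as.integer(d),
                      t = as.integer(t), n = as.integer(n),
                      mutation_mode = mutation_mode),
        seed = as.integer(seed)
      ),
      class = "planted_dataset"
    )
  })
}

#' @export
print.planted_dataset <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "Planted (%d, %d) dataset: t = %d sequences of length n = %d (seed %d)\n",
    p$l, p$d, p$t, p$n, x$seed))
  cat("Motif:", x$motif, "\n")
  print(x$manifest, ...)
  invisible(x)
}

#' @describeIn simulate_planted Tidy a planted dataset: the ground-truth
#'   manifest with the motif attached.
#' @param x A `planted_dataset` object.
#' @param ... Unused.
#' @export
tidy.planted_dataset <- function(x, ...) {
  dplyr::mutate(x$manifest, motif = x$motif)
}

#' @describeIn simulate_planted One-row summary of the dataset.
#' @export
glance.planted_dataset <- function(x, ...) {
  p <- x$params
  tibble::tibble(l = p$l, d = p$d, t = p$t, n = p$n,
                 mutation_mode = p$mutation_mode, seed = x$seed,
                 motif = x$motif)
}

#' Write a planted dataset to FASTA plus a ground-truth manifest
#'
#' @param x A `planted_dataset`.
#' @param fasta Path for the FASTA file.
#' @param manifest Path for the tab-separated manifest
#'   (columns `id`, `position` 0-based, `instance`, `mutations`).
#' @return `x`, invisibly.
#' @export
write_planted <- function(x, fasta, manifest) {
  stopifnot(inherits(x, "planted_dataset"))
  write_fasta(x$sequences, fasta)
  utils::write.table(x$manifest, manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a ground-truth manifest written by [write_planted()]
#'
#' @param path Path to the tab-separated manifest.
#' @return Tibble with columns `id`, `position`, `instance`, `mutations`.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer",
                                         "character", "integer"))
  tibble::as_tibble(df)
}
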