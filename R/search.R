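#' Scan a sequence for windows near an l-mer
#'
#' Returns every window of `seq` within Hamming distance `2d` of `x` — the
#' occurrence set the search engine pairs against and filters. Two motif
#' instances can differ by at most `2d`, so windows farther than `2d` from
#' `x` can never share a motif with it. Windows containing non-ACGT
#' characters are skipped with a warning.
#'
#' @param seq A single DNA sequence (string).
#' @param x The query l-mer.
#' @param d Maximum mutations per motif instance.
#' @return Tibble with columns `position` (0-based offset), `lmer`,
#'   `distance` (each `<= 2d`), in increasing position order.
#' @export
scan_ball <- function(seq, x, d) {
  stopifnot(is.character(seq), length(seq) == 1,
            is.character(x), length(x) == 1)
  check_params(nchar(x), d)
  seq <- toupper(seq)
  if (nchar(seq) < nchar(x)) {
    stop("sequence is shorter than the query l-mer", call. = FALSE)
  }
  sc <- cpp_scan(x, seq, 2L * as.integer(d))
  if (sc$skipped > 0) {
    warning(sc$skipped, " window(s) containing non-ACGT characters skipped",
            call. = FALSE)
  }
  tibble::tibble(position = as.integer(sc$position),
                 lmer = as.character(sc$lmer),
                 distance = as.integer(sc$distance))
}

#' Select the reference sequence for an l-mer
#'
#' Among sequences `2..t`, picks the one minimizing the total number of
#' candidate motifs the pairs with `x` would generate, i.e. the sum over
#' its windows `x'` (within `2d` of `x`) of the cached pair counts
#' `candidate_count(l, d, d_H(x, x'))`. Because counts grow steeply as the
#' pair distance shrinks, this avoids sequences holding near-copies of `x`.
#' Ties break toward the lowest index.
#'
#' @param seqs Sequence set (character vector or tibble with `id`, `seq`);
#'   the first sequence is the one `x` was drawn from and is never chosen.
#' @param x The l-mer from sequence 1.
#' @param d Maximum mutations per motif instance.
#' @return Integer index into `seqs`, in `2..t`.
#' @export
select_reference <- function(seqs, x, d) {
  seqs <- as_sequence_set(seqs, l = nchar(x))
  if (nrow(seqs) < 2) stop("need at least two sequences", call. = FALSE)
  counts <- candidate_count_table(nchar(x), d)$count
  sums <- vapply(2:nrow(seqs), function(i) {
    sc <- cpp_scan(x, seqs$seq[i], 2L * as.integer(d))
    sum(counts[as.integer(sc$distance) + 1L])
  }, numeric(1))
  as.integer(1L + which.min(sums))
}

#' Filtering rule 1: the 2d criterion against both pair members
#'
#' An l-mer `z` can be an instance of a candidate motif shared by `x` and
#' `x_prime` only if it lies within `2d` of both (instances of one motif
#' differ pairwise by at most `2d`). Returns `TRUE` (keep) or `FALSE`
#' (discard, provably not an instance of any shared candidate).
#'
#' @param z Character vector of l-mers to test.
#' @param x,x_prime The pair of l-mers.
#' @param d Maximum mutations per motif instance.
#' @return Logical vector, `TRUE` = keep.
#' @export
rule1 <- function(z, x, x_prime, d) {
  check_params(nchar(x), d)
  hamming_dist(z, x) <= 2 * d & hamming_dist(z, x_prime) <= 2 * d
}

#' Filtering rule 2: the signature-distance criterion
#'
#' Classifies the alignment of `(x, x_prime, z)` by its `(p10, p00)`
#' counts and keeps `z` only if some admissible signature
#' `(alpha, beta)` of the pair (see [mapping_relation()]) satisfies
#' `|p10 - alpha| + |p00 - beta| <= d`. If none does, no member of the
#' pair's candidate set can lie within `d` of `z`, so `z` cannot witness
#' any shared candidate motif. Complements rule 1: each discards words the
#' other cannot.
#'
#' @inheritParams rule1
#' @return Logical vector, `TRUE` = keep.
#' @examples
#' rule2("AAAAAAATTTTTTTT", "AAAAAAAGGGGGGGG", "AAAAAAACCCCCCCC", 4)  # FALSE
#' @export
rule2 <- function(z, x, x_prime, d) {
  l <- nchar(x)
  check_params(l, d)
  rel <- mapping_relation(l, d, hamming_dist(x, x_prime))
  vapply(z, function(zi) {
    if (nrow(rel) == 0) return(FALSE)
    p <- cpp_partition(x, x_prime, zi)
    any(abs(p[["p10"]] - rel$alpha) + abs(p[["p00"]] - rel$beta) <= d)
  }, logical(1), USE.NAMES = FALSE)
}

#' Exact planted (l,d) motif search by l-mer pairs
#'
#' Finds every l-mer `m` such that each input sequence contains a window
#' differing from `m` in at most `d` positions. For each distinct l-mer
#' `x` of sequence 1 a reference sequence is chosen (see
#' [select_reference()]); each window `x'` of the reference within `2d`
#' of `x` forms a pair whose shared candidate set is enumerated
#' deterministically (see [enumerate_candidates()]) and verified against
#' the remaining sequences' windows, pre-filtered by [rule1()] and
#' [rule2()]. The two pair members witness sequence 1 and the reference,
#' so verified candidates are motifs; soundness of the filters and
#' completeness of the pairing make the output exactly the definitional
#' motif set (equal to [brute_force_search()]).
#'
#' @param seqs Sequence set: character vector or tibble with columns `id`
#'   and `seq`; at least two sequences, each of length `>= l`.
#' @param l Motif length in bases.
#' @param d Maximum mutations per instance, `0 <= d < l`.
#' @param score If `TRUE` (default), attach per-motif consensus scores,
#'   relative entropies (dataset background) and per-sequence best
#'   instances to the result.
#' @return An object of class `pair_search`: list with `motifs` (tibble:
#'   `motif`, `max_distance`, and when scored `consensus_score`,
#'   `relative_entropy`), `instances` (tibble: `motif`, `id`, `position`,
#'   `instance`, `distance`), and `params`. Motifs are sorted
#'   lexicographically. Use [tidy()] / [glance()] to extract tibbles.
#' @examples
#' ds <- simulate_planted(l = 8, d = 1, t = 5, n = 40, seed = 7)
#' fit <- pair_search(ds$sequences, l = 8, d = 1)
#' ds$motif %in% fit$motifs$motif
#' @export
pair_search <- function(seqs, l, d, score = TRUE) {
  check_params(l, d)
  seqs <- as_sequence_set(seqs, l = l)
  if (nrow(seqs) < 2) stop("need at least two sequences", call. = FALSE)
  counts <- candidate_count_table(l, d)$count
  res <- cpp_pair_search(seqs$seq, as.integer(l), as.integer(d), counts)
  if (res$skipped > 0) {
    warning(res$skipped, " window(s) containing non-ACGT characters skipped",
            call. = FALSE)
  }
  new_pair_search(res$motifs, seqs, l, d, score)
}

#' Brute-force planted (l,d) motif search over all 4^l patterns
#'
#' The definitional oracle: tests every one of the `4^l` possible l-mers
#' for having a window within distance `d` in every sequence. Exponential
#' in `l` and guarded to `l <= 12`; intended for testing and
#' cross-validation of [pair_search()], which returns the identical set.
#'
#' @inheritParams pair_search
#' @return Character vector of motifs, sorted lexicographically.
#' @export
brute_force_search <- function(seqs, l, d) {
  check_params(l, d)
  if (l > 12) stop("brute force is guarded to l <= 12", call. = FALSE)
  seqs <- as_sequence_set(seqs, l = l)
  res <- cpp_brute_force(seqs$seq, as.integer(l), as.integer(d))
  if (res$skipped > 0) {
    warning(res$skipped, " window(s) containing non-ACGT characters skipped",
            call. = FALSE)
  }
  as.character(res$motifs)
}

new_pair_search <- function(motifs, seqs, l, d, score) {
  motifs <- as.character(motifs)
  if (length(motifs) == 0) {
    inst <- tibble::tibble(motif = character(), id = character(),
                           position = integer(), instance = character(),
                           distance = integer())
    mot <- tibble::tibble(motif = character(), max_distance = integer())
  } else {
    inst <- purrr::map_dfr(motifs, function(m) {
      dplyr::mutate(extract_instances(seqs, m, d), motif = m,
                    .before = 1)
    })
    mot <- inst |>
      dplyr::group_by(.data$motif) |>
      dplyr::summarise(max_distance = max(.data$distance), .groups = "drop")
    if (score) {
      bg <- base_frequencies(seqs)
      sc <- purrr::map_dfr(motifs, function(m) {
        words <- inst$instance[inst$motif == m]
        tibble::tibble(
          motif = m,
          consensus_score = consensus_score(words),
          relative_entropy = relative_entropy(words, background = bg)
        )
      })
      mot <- dplyr::left_join(mot, sc, by = "motif")
    }
  }
  structure(
    list(motifs = mot, instances = inst,
         params = list(l = as.integer(l), d = as.integer(d),
                       t = nrow(seqs), n = nchar(seqs$seq)),
         sequences = seqs),
    class = "pair_search"
  )
}

#' @export
print.pair_search <- function(x, ...) {
  p <- x$params
  cat(sprintf("Planted (%d, %d) motif search: %d sequence(s), %d motif(s)\n",
              p$l, p$d, p$t, nrow(x$motifs)))
  print(x$motifs, ...)
  invisible(x)
}

#' @describeIn pair_search Tidy the fitted search: one row per motif.
#' @param x A `pair_search` object.
#' @param ... Unused.
#' @export
tidy.pair_search <- function(x, ...) x$motifs

#' @describeIn pair_search One-row summary of the search run.
#' @export
glance.pair_search <- function(x, ...) {
  p <- x$params
  tibble::tibble(l = p$l, d = p$d, t = p$t, n_min = min(p$n),
                 n_max = max(p$n), n_motifs = nrow(x$motifs),
                 p_2d = neighborhood_probability(p$l, min(2 * p$d, p$l)))
}

#' Per-sequence best instances of the motifs found by a search
#'
#' @param x A `pair_search` object.
#' @return Tibble with columns `motif`, `id`, `position`, `instance`,
#'   `distance` (one row per motif and sequence).
#' @export
motif_instances <- function(x) {
  stopifnot(inherits(x, "pair_search"))
  x$instances
}
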